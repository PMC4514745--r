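species_id,area_t0_km2,area_t1_km2,net_change_km2,pct_change,d_latitude_km,d_coast_km,d_elevation_m,community
Dicrostonyx groenlandicus,603960,550725,-53235,-6.0,-25,8.3,66.8,cold-climate
Microtus miurus,589108,377223,-211885,-4.3,130,-3.0,167.0,cold-climate
Microtus oeconomus,1083164,823741,-259423,-4.8,105,44.9,88.5,cold-climate
Sorex ugyunak,412527,198763,-213764,-19.7,85,-6.0,-65.8,cold-climate
Microtus longicaudus,206803,336130,129327,10.0,35.0,6.7,32.9,continental
Sorex monticolus,335761,382230,46469,4.0,-595.0,-147.9,108.2,continental
Clethrionomys rutilus,803289,609189,-194100,-31.9,135.0,9.3,105.2,interior
Microtus xanthognathus,355644,219628,-136016,-11.9,45.0,31.7,75.9,interior
Sorex cinereus,1192694,1105717,-86977,-28.5,50.0,11.7,3.7,interior
Sorex hoyi,607161,637943,30782,3.5,130.0,5.9,20.7,interior
Lemmus trimucronatus,702596,395636,-306960,-38.6,210.0,19.7,40.5,northern
Sorex tundrensis,867006,455138,-411868,-65.3,280.0,2.0,5.8,northern
Sorex yukonicus,418908,259669,-159239,-14.8,75.0,-11.6,-47.2,northern
Microtus pennsylvanicus,335399,294218,-41181,-3.5,-90.0,-71.3,-0.9,southern
Sorex palustris,237571,1049427,811856,64.4,85.0,-0.9,-202.4,southern
Synaptomys borealis,532151,979025,446874,46.3,-50.0,-62.9,-19.8,southern
Zapus hudsonius,438181,1010635,572454,54.0,155.0,12.1,115.2,southern
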