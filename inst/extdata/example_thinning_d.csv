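species,d_0,d_1,d_2,d_3,d_4,d_5,d_6,d_7,d_8,d_9,d_10
Abies nephrolepis,29.2,16.5,12.7,6.5,3.9,2.3,1.7,0.7,0.4,NA,NA
Acer mono,0.9,0.2,0.2,0.1,0.2,0.2,0.1,0.0,0.1,NA,0.0
Acer tegmentosum,NA,NA,NA,0.1,0.6,0.7,0.8,0.6,0.2,0.1,NA
Acer ukurunduense,NA,NA,NA,NA,0.2,0.3,NA,NA,NA,NA,NA
Betula costata,17.8,17.2,12.9,9.5,6.6,4.9,4.2,4.2,3.3,3.2,2.2
Euonymus pauciflorus,NA,1.1,1.2,NA,NA,NA,NA,NA,NA,NA,NA
Fraxinus mandshurica,1.2,NA,0.2,3.7,4.6,4.6,3.8,3.0,1.6,1.2,0.6
Pinus koraiensis,58.1,36.4,27.6,17.5,11.6,10.5,10.6,10.2,8.0,6.9,5.3
Tilia amurensis,1.3,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Tilia mandshurica,NA,NA,NA,NA,8.4,11.9,11.4,6.9,NA,NA,NA
Ulmus laciniata,3.7,3.1,1.7,0.3,NA,NA,0.1,NA,0.0,0.2,0.4
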