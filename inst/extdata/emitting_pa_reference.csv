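name,mean_agb_mg_ha,country,forest_area_km2,iucn_cat,corrected_loss_pct,carbon_stock_mg,annual_loss_mg_yr,studentised_residual
Snoul,266.7,Cambodia,103,IV,82.9,1757877,121376,2.8
Sultan Thaha Syaifuddin,247.2,Indonesia,83,VI,73.4,1313292,80331,2.6
Sungai Dumai,128.6,Indonesia,18,V,72.0,148087,8881,2.2
Snoul,262.3,Cambodia,428,IV,69.5,7185222,415977,2.7
Periquito,225.9,Brazil,12,VI,63.4,173512,9164,2.4
Aguateca,161.5,Guatemala,15,II,60.7,155041,7838,2.2
Araras,206.6,Brazil,10,VI,60.1,132225,6622,2.3
Tesso Nilo,218.7,Indonesia,784,II,51.3,10975521,468845,2.5
Bukit Tiban,296.1,Malaysia,59,II,46.4,1118123,43192,2.5
Mutum,233.1,Brazil,105,VI,45.5,1566521,59342,2.4
Mandor,222.5,Indonesia,28,III,39.1,398765,12997,2.2
Maya,147.9,Guatemala,6472,VI,30.4,61240359,1551570,2.1
Bangkiriang,295.0,Indonesia,92,IV,29.2,1736702,42244,2.3
Phnom Kulen,270.5,Cambodia,228,II,28.4,3946778,93536,2.2
Beng Per,203.9,Cambodia,1671,IV,28.0,21810104,508706,2.2
Bien Lac-Nui Ong,218.9,Vietnam,223,IV,27.4,3124029,71431,2.1
Distrito Regional De Manejo Integrado Del Rio Minero,248.6,Colombia,273,VI,24.2,4342716,87442,2.1
Milian-Labau,309.52,Malaysia,15,Ia,23.7,297140,5858,2.0
Jaci-Parani,226.74,Brazil,2067,VI,22.6,29995347,564732,2.2
Triunfo do Xingu,269.63,Brazil,16677,V,21.8,287787642,5226470,2.3
Montanas Mayas Chiquibul,271.4,Guatemala,623,VI,16.9,10822222,151949,2.0
Samlaut,307.1,Cambodia,411,VI,15.7,8077181,105896,2.0
Patuca,270.7,Honduras,3943,II,14.9,68306435,845501,2.1
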