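ID,Binomial,Class,System,Biome,Latitude,Longitude,Units,Red_list_category,1970,1971,1972,1973,1974,1975,1976,1977,1978,1979,1980
1001,Cervus elaphus,Mammalia,terrestrial,temperate broadleaf forest,51.5,-116.0,number of individuals,LC,606,NULL,540,480,NULL,390,310,194,NULL,NULL,NULL
1002,Eretmochelys imbricata,Reptilia,marine,tropical coral,13.2,-59.5,nests,CR,89,102,NULL,150,NULL,201,240,328,NULL,NULL,NULL
1003,Rana temporaria,Amphibia,freshwater,temperate wetland,55.9,-3.2,number of individuals,LC,120,118,115,109,104,99,97,92,88,85,80
1004,Parus major,Aves,terrestrial,temperate broadleaf forest,52.1,0.1,pairs,LC,30,32,NULL,31,33,35,34,36,38,37,39
1005,Salmo trutta,Actinopterygii,freshwater,temperate wetland,56.2,-4.5,index,LC,1.0,1.1,0.9,NULL,1.2,1.0,1.1,NULL,0.95,1.05,1.0
1006,Carcharhinus leucas,Elasmobranchii,marine,tropical coral,-18.1,147.5,number of individuals,NT,14,NULL,NULL,12,NULL,11,NULL,9,NULL,8,NULL
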