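species,accession,sex,group,vol_CH_m3,M_b_kg,mass_source
Struthio camelus,UMZC374,unknown,bird,7.17e-2,60.7,Brassey et al.
Casuarius casuarius,UMZC371.D,unknown,bird,1.72e-2,27.0,Brassey et al.
Dromaius novaehollandiae,UMZC363,unknown,bird,2.14e-2,20.06,Brassey et al.
Rhea americana,UMZC378.gg,unknown,bird,1.77e-2,16.3,Brassey et al.
Rhea pennata,UMZC378ki,unknown,bird,1.59e-2,14.9,Brassey et al.
Apteryx australis,UMZC378.A,unknown,bird,1.10e-3,2.96,Brassey et al.
Apteryx australis lawryi,UMZC378.SS,F,bird,1.40e-3,2.41,Brassey et al.
Branta leucopsis,,unknown,bird,1.10e-3,1.69,carcass weight
Numida meleagris,,F,bird,1.00e-3,1.40,carcass weight
Bison bison,OUMNH17430,M,non-primate mammal,4.73e-1,558.5,Bates et al.
Bos taurus,OUMNH17432,unknown,non-primate mammal,2.19e-1,323.7,Bates et al.
Camelus dromedaries,OUMNH17427,unknown,non-primate mammal,3.21e-1,427.0,Bates et al.
Cervus elaphus,OUMNH17431,M,non-primate mammal,8.40e-2,89.5,Bates et al.
Dicerorhinus sumatrensis,OUMNH4139,unknown,non-primate mammal,3.61e-1,470.3,Bates et al.
Elephas maximus,OUMNH10686,M,non-primate mammal,2.09e0,2352.0,Bates et al.
Equus caballus,OUMNH17428,unknown,non-primate mammal,3.70e-1,517.5,Bates et al.
Giraffa camelopardalis,OUMNH19507,unknown,non-primate mammal,4.35e-1,638.2,Bates et al.
Loxodonta africana,OUMNH4004,unknown,non-primate mammal,2.75e0,2734.9,Bates et al.
Megaloceros giganteus,OUMNH17433,unknown,non-primate mammal,3.01e-1,435.6,Bates et al.
Rangifer tarandus,OUMNH17529,unknown,non-primate mammal,7.57e-2,95.8,Bates et al.
Sus scrofa,OUMNH17426,unknown,non-primate mammal,7.79e-2,107.4,Bates et al.
Tapirus indicus,OUMNH17425,unknown,non-primate mammal,1.70e-1,295.3,Bates et al.
Ursus maritimus,OUMNH17459,unknown,non-primate mammal,1.11e-1,206.1,Bates et al.
Chlorocebus aethiops,KUPRI28,M,primate,3.70e-3,3.78,carcass weight
Macaca fuscata,KUPRI375,F,primate,5.10e-3,6.60,carcass weight
Saimiri sciureus,KUPRI290,F,primate,6.00e-4,0.759,carcass weight
Hylobates agilis,KUPRI277,M,primate,5.40e-3,6.75,carcass weight
Hylobates lar,KUPRI182,F,primate,6.60e-3,6.65,Ruff et al.
Gorilla gorilla,KUPRI298-317,M,primate,9.57e-2,176.0,carcass weight
Pan troglodytes,,M,primate,4.18e-2,50.9,Ruff et al.
Pongo pygmaeus,,F,primate,3.25e-2,45.0,carcass weight
Homo sapiens,NLM,M,primate,4.91e-2,68.9,carcass weight
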