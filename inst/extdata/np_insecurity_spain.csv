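species,group,insecurity,times_actual_gt_random
Chioglossa lusitanica,amphibian,0.992,11
Euproctus asper,amphibian,0.984,20
Pleurodeles waltl,amphibian,0.993,4
Bufo calamita,amphibian,0.992,15
Hyla meridionalis,amphibian,0.991,15
Rana iberica,amphibian,0.988,20
Rana pyrenaica,amphibian,0.875,20
Emys orbicularis,reptile,0.993,6
Mauremys leprosa,reptile,0.993,5
Testudo graeca,reptile,0.952,20
Anguis fragilis,reptile,0.991,20
Podarcis muralis,reptile,0.986,20
Elaphe scalaris,reptile,0.994,0
Phalacrocorax aristotelis,bird,0.992,15
Ciconia nigra,bird,0.993,10
Netta rufina,bird,0.994,3
Gypaetus barbatus,bird,0.981,20
Neophron percnopterus,bird,0.992,14
Aegypus monachus,bird,0.984,20
Aquila adalberti,bird,0.982,20
Aquila chrysaetos,bird,0.989,20
Lagopus mutus,bird,0.951,20
Tetrao urogallus,bird,0.973,20
Perdix perdix,bird,0.976,20
Otis tarda,bird,0.997,0
Picus viridis,bird,0.992,13
Pyrrhocorax graculus,bird,0.979,20
Pyrrhocorax pyrrhocorax,bird,0.989,20
Galemys pyrenaicus,mammal,0.989,20
Canis lupus,mammal,0.991,18
Lutra lutra,mammal,0.991,20
Ursus arctos,mammal,0.979,20
Felis silvestris,mammal,0.989,20
Lynx pardinus,mammal,0.976,20
Cervus elaphus,mammal,0.991,20
Rupicapra pyrenaica,mammal,0.975,20
Capra pyrenaica,mammal,0.990,20
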