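species,scientific_name,n_original,n_final
American Goldfinch,Spinus tristis,236217,2663
Anna's Hummingbird,Calypte anna,32047,427
Baird's Sparrow,Ammodramus bairdii,513,48
Band-tailed Pigeon,Patagioenas fasciata,17415,407
Black-capped Chickadee,Poecile atricapillus,131634,1877
Blue-winged Teal,Anas discors,15288,1243
Bobolink,Dolichonyx oryzivorus,28658,1105
Brown-headed Cowbird,Molothrus ater,178324,3996
Brown Thrasher,Toxostoma rufum,61661,2254
Cactus Wren,Campylorhynchus brunneicapillus,4714,215
Carolina Wren,Thryothorus ludovicianus,107244,1893
Chestnut-collared Longspur,Calcarius ornatus,1426,105
Dickcissel,Spiza americana,29479,1411
Downy Woodpecker,Picoides pubescens,150261,2925
Eastern Kingbird,Tyrannus tyrannus,111057,2956
Ferruginous Hawk,Buteo regalis,1587,238
Gambel's Quail,Callipepla gambelii,6307,198
Grasshopper Sparrow,Ammodramus savannarum,23254,1323
Gray Partridge,Perdix perdix,616,129
Gray Vireo,Vireo vicinior,265,43
Great Blue Heron,Ardea herodias,141552,3449
Great Horned Owl,Bubo virginianus,11130,1487
Green-winged Teal,Anas carolinensis,6726,530
Hooded Warbler,Wilsonia citrina,15482,773
Lark Bunting,Calamospiza melanocorys,3268,355
Lark Sparrow,Chondestes grammacus,20978,1467
Northern Harrier,Circus cyaneus,14795,1231
Northern Pintail,Anas acuta,4269,466
Orchard Oriole,Icterus spurius,41136,1876
Painting Bunting,Passerina ciris,15294,569
Pied-billed Grebe,Podilymbus podiceps,23272,1287
Pileated Woodpecker,Dryocopus pileatus,48118,1982
Pygmy Nuthatch,Sitta pygmaea,11848,322
Red-eyed Vireo,Vireo olivaceus,138887,2389
Red-headed Woodpecker,Melanerpes erythrocephalus,22809,1593
Red-tailed Hawk,Buteo jamaicensis,101388,3715
Ruby-throated Hummingbird,Archilochus colubris,81241,2090
Savannah Sparrow,Passerculus sandwichensis,41214,1435
Scissor-tailed Flycatcher,Tyrannus forficatus,16571,718
Sedge Wren,Cistothorus platensis,7827,478
Sharp-tailed Grouse,Tympanuchus phasianellus,801,121
Short-eared Owl,Asio flammeus,760,139
Sora,Porzana carolina,6687,649
Tufted Titmouse,Baeolophus bicolor,129472,2058
Vesper Sparrow,Pooecetes gramineus,16387,1164
Western Kingbird,Tyrannus verticalis,45319,2028
Western Meadowlark,Sturnella neglecta,36755,1825
Western Tanager,Piranga ludoviciana,33108,1127
White-headed Woodpecker,Picoides albolarvatus,4389,137
Yellow-headed Blackbird,Xanthocephalus xanthocephalus,16794,1031
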