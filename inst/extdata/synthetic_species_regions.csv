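species,family,region,related_affinity
Corvidae_like_sp1,Corvidae_like,Nearctic,northern
Corvidae_like_sp2,Corvidae_like,Nearctic,northern
Corvidae_like_sp3,Corvidae_like,Nearctic,northern
Corvidae_like_sp4,Corvidae_like,Nearctic,northern
Corvidae_like_sp5,Corvidae_like,Nearctic,northern
Corvidae_like_sp6,Corvidae_like,Nearctic,northern
Corvidae_like_sp7,Corvidae_like,Nearctic,northern
Corvidae_like_sp8,Corvidae_like,Nearctic,northern
Corvidae_like_sp9,Corvidae_like,Palearctic,northern
Corvidae_like_sp10,Corvidae_like,Palearctic,northern
Corvidae_like_sp11,Corvidae_like,Palearctic,northern
Corvidae_like_sp12,Corvidae_like,Neotropics,northern
Troglodytidae_like_sp1,Troglodytidae_like,Nearctic,northern
Troglodytidae_like_sp2,Troglodytidae_like,Nearctic,northern
Troglodytidae_like_sp3,Troglodytidae_like,Nearctic,northern
Troglodytidae_like_sp4,Troglodytidae_like,Nearctic,northern
Troglodytidae_like_sp5,Troglodytidae_like,Nearctic,northern
Troglodytidae_like_sp6,Troglodytidae_like,Neotropics,northern
Troglodytidae_like_sp7,Troglodytidae_like,Neotropics,northern
Troglodytidae_like_sp8,Troglodytidae_like,Neotropics,northern
Troglodytidae_like_sp9,Troglodytidae_like,Mexican Transition Zone,northern
Furnariidae_like_sp1,Furnariidae_like,Neotropics,neotropical
Furnariidae_like_sp2,Furnariidae_like,Neotropics,neotropical
Furnariidae_like_sp3,Furnariidae_like,Neotropics,neotropical
Furnariidae_like_sp4,Furnariidae_like,Neotropics,neotropical
Furnariidae_like_sp5,Furnariidae_like,Neotropics,neotropical
Furnariidae_like_sp6,Furnariidae_like,Neotropics,neotropical
Furnariidae_like_sp7,Furnariidae_like,Neotropics,neotropical
Furnariidae_like_sp8,Furnariidae_like,Neotropics,neotropical
Furnariidae_like_sp9,Furnariidae_like,Neotropics,neotropical
Furnariidae_like_sp10,Furnariidae_like,Mexican Transition Zone,neotropical
Thraupidae_like_sp1,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp2,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp3,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp4,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp5,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp6,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp7,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp8,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp9,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp10,Thraupidae_like,Neotropics,neotropical
Thraupidae_like_sp11,Thraupidae_like,Mesoamerican dominion,neotropical
Thraupidae_like_sp12,Thraupidae_like,Mesoamerican dominion,neotropical
Emberizidae_like_sp1,Emberizidae_like,Mexican Transition Zone,neotropical
Emberizidae_like_sp2,Emberizidae_like,Mexican Transition Zone,neotropical
Emberizidae_like_sp3,Emberizidae_like,Mexican Transition Zone,neotropical
Emberizidae_like_sp4,Emberizidae_like,Mexican Transition Zone,neotropical
Emberizidae_like_sp5,Emberizidae_like,Mexican Transition Zone,neotropical
Emberizidae_like_sp6,Emberizidae_like,Mexican Transition Zone,neotropical
Emberizidae_like_sp7,Emberizidae_like,Mesoamerican dominion,neotropical
Emberizidae_like_sp8,Emberizidae_like,Mesoamerican dominion,neotropical
Emberizidae_like_sp9,Emberizidae_like,Neotropics,neotropical
Emberizidae_like_sp10,Emberizidae_like,Neotropics,neotropical
Emberizidae_like_sp11,Emberizidae_like,Neotropics,neotropical
Emberizidae_like_sp12,Emberizidae_like,Nearctic,neotropical
Cracidae_like_sp1,Cracidae_like,Mesoamerican dominion,neotropical
Cracidae_like_sp2,Cracidae_like,Mesoamerican dominion,neotropical
Cracidae_like_sp3,Cracidae_like,Mesoamerican dominion,neotropical
Cracidae_like_sp4,Cracidae_like,Mesoamerican dominion,neotropical
Cracidae_like_sp5,Cracidae_like,Mesoamerican dominion,neotropical
Cracidae_like_sp6,Cracidae_like,Neotropics,neotropical
Cracidae_like_sp7,Cracidae_like,Neotropics,neotropical
Cracidae_like_sp8,Cracidae_like,Neotropics,neotropical
Cracidae_like_sp9,Cracidae_like,Neotropics,neotropical
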