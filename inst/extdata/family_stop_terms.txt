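Acrididae
Aleyrodidae
Andrenidae
Anthophoridae
Aphididae
Apidae
Aphelinidae
Agromyzidae
Anisopodidae
Anobiidae
Anthomyiidae
Asilidae
Baetidae
Bibionidae
Blattidae
Blattellidae
Blaberidae
Bombycidae
Bombyliidae
Bostrichidae
Braconidae
Brentidae
Buprestidae
Calliphoridae
Carabidae
Cecidomyiidae
Cerambycidae
Ceratopogonidae
Chalcididae
Chironomidae
Chrysomelidae
Chrysopidae
Cicadellidae
Cicadidae
Cimicidae
Coccinellidae
Coenagrionidae
Coreidae
Crambidae
Cryptophagidae
Culicidae
Curculionidae
Cynipidae
Danaidae
Delphacidae
Dermestidae
Diaspididae
Diprionidae
Dolichopodidae
Drosophilidae
Dryophthoridae
Dytiscidae
Elateridae
Encyrtidae
Ephemeridae
Ephydridae
Erebidae
Eulophidae
Eurytomidae
Figitidae
Formicidae
Forficulidae
Fulgoridae
Gelechiidae
Geometridae
Gerridae
Glossinidae
Gryllidae
Gryllotalpidae
Halictidae
Hesperiidae
Hippoboscidae
Hydrophilidae
Ichneumonidae
Isotomidae
Lampyridae
Libellulidae
Lucanidae
Lycaenidae
Lygaeidae
Machilidae
Megachilidae
Meloidae
Membracidae
Miridae
Muscidae
Mycetophilidae
Nitidulidae
Noctuidae
Notodontidae
Nymphalidae
Oestridae
Orussidae
Papilionidae
Pediculidae
Pentatomidae
Phoridae
Pieridae
Platygastridae
Plutellidae
Psychodidae
Psyllidae
Pteromalidae
Pulicidae
Pyralidae
Reduviidae
Rhagionidae
Rhinotermitidae
Saturniidae
Scarabaeidae
Sciaridae
Sepsidae
Silphidae
Simuliidae
Siricidae
Sminthuridae
Sphecidae
Sphingidae
Staphylinidae
Stratiomyidae
Syrphidae
Tabanidae
Tachinidae
Tenebrionidae
Tenthredinidae
Tephritidae
Termitidae
Tettigoniidae
Thripidae
Tineidae
Tipulidae
Tortricidae
Triozidae
Trichogrammatidae
Vespidae
Zygaenidae
Hominidae
Muridae
Cricetidae
Bovidae
Suidae
Canidae
Felidae
Equidae
Salmonidae
Cyprinidae
Danionidae
Xenopodidae
Phasianidae
Anatidae
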