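sample_id	label_species	product_type	catch_area	qpcr_result	seq_id_1	seq_id_2
1415	Cod	breaded fillet	Atlantic	NEGATIVE	Gadus_macrocephalus	Gadus_macrocephalus
1426	Cod	breaded fillet	Atlantic	NEGATIVE	Gadus_macrocephalus	Gadus_macrocephalus
1446	Cod	breaded fillet	Atlantic	NEGATIVE	Gadus_macrocephalus	Gadus_macrocephalus
1747	Cod	precooked meal	Atlantic	NEGATIVE	Gadus_macrocephalus	Gadus_macrocephalus
1889	Cod	precooked meal	Atlantic	NEGATIVE	Gadus_macrocephalus	Gadus_macrocephalus
1975	Cod	breaded fillet	Atlantic	NEGATIVE	Gadus_macrocephalus	Gadus_macrocephalus
1886	Cod	fish cakes	NA	INCONCLUSIVE	Gadus_morhua	Melanogrammus_aeglefinus
1765	Cod	fish cakes	NA	HADDOCK	Melanogrammus_aeglefinus	Melanogrammus_aeglefinus
1892	Cod	fish fingers	NA	COD	Gadus_chalcogrammus	Gadus_morhua
1470	Haddock	precooked meal	Atlantic	COD	Gadus_morhua	Gadus_morhua
1812	Haddock	fish cakes	Atlantic	COD	Gadus_morhua	Gadus_morhua
1888	Haddock	precooked meal	Atlantic	COD	Gadus_morhua	Gadus_morhua
1977	Haddock	breaded fillet	Atlantic	COD	Gadus_morhua	Gadus_morhua
1989	Haddock	precooked meal	Atlantic	COD	Gadus_morhua	Gadus_morhua
1868	Haddock	precooked meal	Atlantic	COD	Gadus_morhua	Gadus_morhua
1851	Haddock	precooked meal	Atlantic	NEGATIVE	Gadus_macrocephalus	Gadus_macrocephalus
1452	Haddock	fish cakes	Atlantic	INCONCLUSIVE	Gadus_morhua	Melanogrammus_aeglefinus
1847	Haddock	fish cakes	Atlantic	INCONCLUSIVE	Gadus_morhua	Melanogrammus_aeglefinus
1763	Alaskan Pollack	fish cakes	Pacific	NEGATIVE	Pangasius_hypophthalmus	Gadus_chalcogrammus
1813	Hake (M. capensis)	breaded fillet	NA	NEGATIVE	Merluccius_paradoxus	Merluccius_paradoxus
1848	Whiting	precooked meal	NA	INCONCLUSIVE	Micromesistius_poutassou	Micromesistius_poutassou
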