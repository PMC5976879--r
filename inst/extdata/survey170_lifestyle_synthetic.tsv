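species	lifestyle	bsh	pva
Lactobacillus acidophilus	vertebrate-adapted	1	1
Lactobacillus agilis	vertebrate-adapted	1	0
Lactobacillus amylovorus	vertebrate-adapted	1	0
Lactobacillus animalis	vertebrate-adapted	1	0
Lactobacillus antri	vertebrate-adapted	1	0
Lactobacillus apodemi	vertebrate-adapted	1	0
Lactobacillus aviarius	vertebrate-adapted	1	0
Lactobacillus coleohominis	vertebrate-adapted	1	0
Lactobacillus crispatus	vertebrate-adapted	1	1
Lactobacillus delbrueckii	vertebrate-adapted	1	0
Lactobacillus equicursoris	vertebrate-adapted	1	0
Lactobacillus frumenti	vertebrate-adapted	1	0
Lactobacillus gallinarum	vertebrate-adapted	1	0
Lactobacillus gasseri	vertebrate-adapted	1	1
Lactobacillus gigeriorum	vertebrate-adapted	1	0
Lactobacillus gorillae	unknown	1	0
Lactobacillus hamsteri	vertebrate-adapted	1	0
Lactobacillus helveticus	vertebrate-adapted	1	0
Lactobacillus hominis	vertebrate-adapted	1	0
Lactobacillus ingluviei	vertebrate-adapted	1	0
Lactobacillus intestinalis	vertebrate-adapted	1	0
Lactobacillus johnsonii	vertebrate-adapted	1	1
Lactobacillus kalixensis	vertebrate-adapted	1	0
Lactobacillus kefiranofaciens	vertebrate-adapted	1	0
Lactobacillus kitasatonis	vertebrate-adapted	1	0
Lactobacillus mucosae	vertebrate-adapted	1	0
Lactobacillus murinus	vertebrate-adapted	1	0
Lactobacillus oris	vertebrate-adapted	1	0
Lactobacillus panis	vertebrate-adapted	1	0
Lactobacillus plantarum	nomadic	1	1
Lactobacillus reuteri	vertebrate-adapted	1	1
Lactobacillus rogosae	unknown	1	0
Lactobacillus ruminis	vertebrate-adapted	1	0
Lactobacillus saerimneri	unknown	1	0
Lactobacillus salivarius	vertebrate-adapted	1	1
Lactobacillus secaliphilus	unknown	1	0
Lactobacillus taiwanensis	vertebrate-adapted	1	0
Lactobacillus ultunensis	vertebrate-adapted	1	0
Lactobacillus vaginalis	unknown	1	1
Lactobacillus synthsp001	vertebrate-adapted	0	1
Lactobacillus synthsp002	vertebrate-adapted	0	1
Lactobacillus synthsp003	vertebrate-adapted	0	1
Lactobacillus synthsp004	vertebrate-adapted	0	1
Lactobacillus synthsp005	vertebrate-adapted	0	1
Lactobacillus synthsp006	free-living	0	1
Lactobacillus synthsp007	free-living	0	1
Lactobacillus synthsp008	free-living	0	1
Lactobacillus synthsp009	free-living	0	1
Lactobacillus synthsp010	free-living	0	1
Lactobacillus synthsp011	free-living	0	1
Lactobacillus synthsp012	free-living	0	1
Lactobacillus synthsp013	free-living	0	1
Lactobacillus synthsp014	free-living	0	1
Lactobacillus synthsp015	free-living	0	1
Lactobacillus synthsp016	free-living	0	1
Lactobacillus synthsp017	free-living	0	1
Lactobacillus synthsp018	free-living	0	1
Lactobacillus synthsp019	free-living	0	1
Lactobacillus synthsp020	free-living	0	1
Lactobacillus synthsp021	free-living	0	1
Lactobacillus synthsp022	free-living	0	1
Lactobacillus synthsp023	free-living	0	1
Lactobacillus synthsp024	free-living	0	1
Lactobacillus synthsp025	free-living	0	1
Lactobacillus synthsp026	free-living	0	1
Lactobacillus synthsp027	free-living	0	1
Lactobacillus synthsp028	free-living	0	1
Lactobacillus synthsp029	free-living	0	1
Lactobacillus synthsp030	free-living	0	1
Lactobacillus synthsp031	free-living	0	1
Lactobacillus synthsp032	free-living	0	1
Lactobacillus synthsp033	free-living	0	1
Lactobacillus synthsp034	free-living	0	1
Lactobacillus synthsp035	free-living	0	1
Lactobacillus synthsp036	free-living	0	1
Lactobacillus synthsp037	free-living	0	1
Lactobacillus synthsp038	free-living	0	1
Lactobacillus synthsp039	unknown	0	1
Lactobacillus synthsp040	unknown	0	1
Lactobacillus synthsp041	unknown	0	1
Lactobacillus synthsp042	unknown	0	1
Lactobacillus synthsp043	unknown	0	1
Lactobacillus synthsp044	unknown	0	1
Lactobacillus synthsp045	unknown	0	1
Lactobacillus synthsp046	unknown	0	1
Lactobacillus synthsp047	unknown	0	1
Lactobacillus synthsp048	unknown	0	1
Lactobacillus synthsp049	unknown	0	1
Lactobacillus synthsp050	unknown	0	1
Lactobacillus synthsp051	unknown	0	1
Lactobacillus synthsp052	unknown	0	1
Lactobacillus synthsp053	unknown	0	1
Lactobacillus synthsp054	unknown	0	1
Lactobacillus synthsp055	unknown	0	1
Lactobacillus synthsp056	unknown	0	1
Lactobacillus synthsp057	unknown	0	1
Lactobacillus synthsp058	unknown	0	1
Lactobacillus synthsp059	unknown	0	1
Lactobacillus synthsp060	unknown	0	1
Lactobacillus synthsp061	unknown	0	1
Lactobacillus synthsp062	unknown	0	1
Lactobacillus synthsp063	unknown	0	1
Lactobacillus synthsp064	unknown	0	1
Lactobacillus synthsp065	unknown	0	1
Lactobacillus synthsp066	unknown	0	1
Lactobacillus synthsp067	unknown	0	1
Lactobacillus synthsp068	unknown	0	1
Lactobacillus synthsp069	unknown	0	1
Lactobacillus synthsp070	unknown	0	1
Lactobacillus synthsp071	nomadic	0	1
Lactobacillus synthsp072	nomadic	0	1
Lactobacillus synthsp073	nomadic	0	1
Lactobacillus synthsp074	nomadic	0	1
Lactobacillus synthsp075	free-living	0	0
Lactobacillus synthsp076	free-living	0	0
Lactobacillus synthsp077	free-living	0	0
Lactobacillus synthsp078	free-living	0	0
Lactobacillus synthsp079	free-living	0	0
Lactobacillus synthsp080	free-living	0	0
Lactobacillus synthsp081	free-living	0	0
Lactobacillus synthsp082	free-living	0	0
Lactobacillus synthsp083	free-living	0	0
Lactobacillus synthsp084	free-living	0	0
Lactobacillus synthsp085	free-living	0	0
Lactobacillus synthsp086	free-living	0	0
Lactobacillus synthsp087	free-living	0	0
Lactobacillus synthsp088	free-living	0	0
Lactobacillus synthsp089	free-living	0	0
Lactobacillus synthsp090	free-living	0	0
Lactobacillus synthsp091	free-living	0	0
Lactobacillus synthsp092	free-living	0	0
Lactobacillus synthsp093	free-living	0	0
Lactobacillus synthsp094	free-living	0	0
Lactobacillus synthsp095	unknown	0	0
Lactobacillus synthsp096	unknown	0	0
Lactobacillus synthsp097	unknown	0	0
Lactobacillus synthsp098	unknown	0	0
Lactobacillus synthsp099	unknown	0	0
Lactobacillus synthsp100	unknown	0	0
Lactobacillus synthsp101	unknown	0	0
Lactobacillus synthsp102	unknown	0	0
Lactobacillus synthsp103	unknown	0	0
Lactobacillus synthsp104	unknown	0	0
Lactobacillus synthsp105	unknown	0	0
Lactobacillus synthsp106	unknown	0	0
Lactobacillus synthsp107	unknown	0	0
Lactobacillus synthsp108	unknown	0	0
Lactobacillus synthsp109	unknown	0	0
Lactobacillus synthsp110	unknown	0	0
Lactobacillus synthsp111	unknown	0	0
Lactobacillus synthsp112	unknown	0	0
Lactobacillus synthsp113	unknown	0	0
Lactobacillus synthsp114	unknown	0	0
Lactobacillus synthsp115	vertebrate-adapted	0	0
Lactobacillus synthsp116	vertebrate-adapted	0	0
Lactobacillus synthsp117	vertebrate-adapted	0	0
Lactobacillus synthsp118	vertebrate-adapted	0	0
Lactobacillus synthsp119	vertebrate-adapted	0	0
Lactobacillus synthsp120	vertebrate-adapted	0	0
Lactobacillus synthsp121	vertebrate-adapted	0	0
Lactobacillus synthsp122	vertebrate-adapted	0	0
Lactobacillus synthsp123	vertebrate-adapted	0	0
Lactobacillus synthsp124	vertebrate-adapted	0	0
Lactobacillus synthsp125	insect-adapted	0	0
Lactobacillus synthsp126	insect-adapted	0	0
Lactobacillus synthsp127	insect-adapted	0	0
Lactobacillus synthsp128	insect-adapted	0	0
Lactobacillus synthsp129	nomadic	0	0
Lactobacillus synthsp130	nomadic	0	0
Lactobacillus synthsp131	nomadic	0	0
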