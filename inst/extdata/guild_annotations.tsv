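genus	guild	module	ko_ids
Thermodesulfovibrio	sulfate_reduction	M00596	K00958;K00394;K00395;K11180;K11181
Desulfotomaculum	sulfate_reduction	M00596	K00958;K00394;K00395;K11180;K11181
Desulfocucumis	sulfate_reduction	M00596	K00958;K00394;K00395;K11180;K11181
Desulfofarcimen	sulfate_reduction	M00596	K00958;K00394;K00395;K11180;K11181
Desulfocurvus	sulfate_reduction	M00596	K00958;K00394;K00395;K11180;K11181
Desulfolutivibrio	sulfate_reduction	M00596	K00958;K00394;K00395;K11180;K11181
Methanothermobacter	methanogenesis	M00567	K00399;K00401;K00402
Methanobacterium	methanogenesis	M00567	K00399;K00401;K00402
Acetobacterium	wood_ljungdahl	M00377	K00198;K14138;K15022
Moorella	wood_ljungdahl	M00377	K00198;K14138;K15022
Rectinema	fermentation	FERM	K00016;K00656;K01568
Caldicoprobacter	fermentation	FERM	K00016;K00656;K01568
Pelotomaculum	fermentation	FERM	K00016;K00656;K01568
Tepidanaerobacter	fermentation	FERM	K00016;K00656;K01568
Anaerovorax	fermentation	FERM	K00016;K00656;K01568
Macellibacteroides	fermentation	FERM	K00016;K00656;K01568
Marcellibacteroides	fermentation	FERM	K00016;K00656;K01568
Proteiniphilum	fermentation	FERM	K00016;K00656;K01568
OPB41	wood_ljungdahl	M00377	K00198;K14138;K15022
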