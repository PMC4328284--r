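group	family	species	n_specimens	fossil
Fissiped	Eupleridae	Cryptoprocta ferox	1	0
Fissiped	Eupleridae	Eupleres goudotii	2	0
Fissiped	Eupleridae	Fossa fossana	2	0
Fissiped	Eupleridae	Galidia elegans	2	0
Fissiped	Felidae	Acinonyx jubatus	2	0
Fissiped	Felidae	Felis bengalensis	2	0
Fissiped	Felidae	Felis vivverina	2	0
Fissiped	Felidae	Lynx rufus	2	0
Fissiped	Herpestidae	Cynictis penicillata	1	0
Fissiped	Herpestidae	Ichneumia albicauda	1	0
Fissiped	Hyaenidae	Crocuta crocuta	2	0
Fissiped	Hyaenidae	Proteles cristatus	2	0
Fissiped	Nandinidae	Nandinia binotata	2	0
Fissiped	Viverridae	Civettictis civetta	2	0
Fissiped	Viverridae	Genetta genetta	2	0
Fissiped	Viverridae	Paradoxurus hermaphroditus	2	0
Fissiped	Canidae	Canis lupus	2	0
Fissiped	Canidae	Cerdocyon thous	2	0
Fissiped	Canidae	Otocyon megalotis	2	0
Fissiped	Canidae	Vulpes vulpes	2	0
Fissiped	Mephitidae	Mephitis mephitis	2	0
Fissiped	Mustelidae	Enhydra lutris	2	0
Fissiped	Ailuridae	Ailurus fulgens	1	0
Fissiped	Mustelidae	Gulo gulo	1	0
Fissiped	Mustelidae	Martes pennanti	2	0
Fissiped	Mustelidae	Meles meles	2	0
Fissiped	Procyonidae	Nasua nasua	2	0
Fissiped	Procyonidae	Potos flavus	2	0
Fissiped	Procyonidae	Procyon cancrivorous	2	0
Fissiped	Procyonidae	Procyon lotor	2	0
Fissiped	Ursidae	Ailuropoda melanoleuca	2	0
Fissiped	Ursidae	Melursus ursinus	1	0
Fissiped	Ursidae	Tremarctos ornatus	2	0
Fissiped	Ursidae	Ursus americanus	2	0
Pinniped	Desmatophocidae	Allodesmus sp.	1	1
Pinniped	Enaliarctinae	Enaliarctos emlongi	1	1
Pinniped	Odobenidae	Odobenus rosmarus	3	0
Pinniped	Odobenidae	Pontolis magnus	1	1
Pinniped	Otariidae	Arctocephalus australis	2	0
Pinniped	Otariidae	Arctocephalus galapogoensis	1	0
Pinniped	Otariidae	Arctocephalus gazella	5	0
Pinniped	Otariidae	Arctocephalus philippi	1	0
Pinniped	Otariidae	Arctocephalus pussillus	3	0
Pinniped	Otariidae	Arctocephalus tropacalis	2	0
Pinniped	Otariidae	Callorhinus ursinus	2	0
Pinniped	Otariidae	Eumetopias jubatus	3	0
Pinniped	Otariidae	Neophoca cinerea	1	0
Pinniped	Otariidae	Otaria flavescens	3	0
Pinniped	Otariidae	Zalophus californianus	1	0
Pinniped	Phocidae	Acrophoca longirostris	1	1
Pinniped	Phocidae	Piscophoca pacifica	1	1
Pinniped	Phocidae	Cystophora cristata	3	0
Pinniped	Phocidae	Erignathus barbatus	1	0
Pinniped	Phocidae	Halichoerus grypus	5	0
Pinniped	Phocidae	Histriophoca fasciata	7	0
Pinniped	Phocidae	Hydrurga leptonyx	2	0
Pinniped	Phocidae	Leptonychotes weddelli	3	0
Pinniped	Phocidae	Lobodon carcinophagus	4	0
Pinniped	Phocidae	Mirounga leonina	3	0
Pinniped	Phocidae	Monachus monachus	2	0
Pinniped	Phocidae	Ommatophoca rossi	2	0
Pinniped	Phocidae	Pagophilus groenlandica	1	0
Pinniped	Phocidae	Phoca hispida	4	0
Pinniped	Phocidae	Phoca largha	4	0
Pinniped	Phocidae	Phoca vitulina	2	0
Pinniped	Phocidae	Pusa caspica	4	0
Pinniped	Phocidae	Pusa sibirica	4	0
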