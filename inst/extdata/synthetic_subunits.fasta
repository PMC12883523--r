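>a|S1|alpha|F1
SVDYGYMIILGGPENKRWENMGIASELEFVKDKGQPNAREQINTTNLKRPKFESLAVTIEYSKVISKNLFVQVVKYFENHEPEVRGPASAGLIFNNKEQDIVSWIGAKMDCRVEALRAKIWKKGRKTGGDDLLIMDDTCTPDGSRKGRAF
>b|S1|beta|F1
IDVKTGTLSGSYKNFELVRVIQFEEYIRDYSGFTFGRRMTPEAMSDAQVNSGTSGTDASRHARHQSIHHVSAVTMTSLEFVAVIEPPTEKSDYAEGEAKMRMKDKASTVMTVSNPALRIGLAEGSGSGKNLTFVLAVAAGGACVTPAALMPAKKVWGQLEAGQRSKLVCIPVEWFHQNSRWSEQL
>Lc|S1|linker|F1
VKADCWGTEPSKGVRKLNECSQLFKAVQSDQLPPKEDMGGEVFGKEDICGSNQAHAAMTAVIVVAIGHYM
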