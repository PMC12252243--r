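taxon	rank	trait
Archaeplastida	supergroup	phototrophic
Chlorophyta	division	phototrophic
Chlorophyceae	class	phototrophic
Trebouxiophyceae	class	phototrophic
Bacillariophyta	class	phototrophic
Chrysophyceae	class	phototrophic
Euglenida	class	phototrophic
Scenedesmus	genus	phototrophic
Chlamydomonas	genus	phototrophic
Stramenopiles	supergroup	consumer
Alveolata	supergroup	consumer
Rhizaria	supergroup	consumer
Amoebozoa	supergroup	consumer
Ciliophora	division	consumer
Cercozoa	division	consumer
Dinoflagellata	division	consumer
Bicoecea	class	consumer
Colpoda	genus	consumer
Oxytricha	genus	consumer
Cercomonas	genus	consumer
Apicomplexa	division	parasitic
Oomycota	division	parasitic
Peronosporomycetes	class	parasitic
Phytomyxea	class	parasitic
Syndiniales	order	parasitic
Pythium	genus	parasitic
Phytophthora	genus	parasitic
Plasmodiophora	genus	parasitic
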