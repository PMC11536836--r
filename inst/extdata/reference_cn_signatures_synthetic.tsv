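channel	CN1	CN2
homdel:0-100kb	0	0
homdel:100kb-1Mb	0	0
homdel:>1Mb	0	0
LOH:1:0-100kb	0	0
LOH:1:100kb-1Mb	0	0
LOH:1:1-10Mb	0.05273	0
LOH:1:10-40Mb	0.06328	0
LOH:1:>40Mb	0	0
LOH:2:0-100kb	0	0
LOH:2:100kb-1Mb	0	0
LOH:2:1-10Mb	0.04218	0
LOH:2:10-40Mb	0	0
LOH:2:>40Mb	0	0
LOH:3-4:0-100kb	0	0
LOH:3-4:100kb-1Mb	0	0
LOH:3-4:1-10Mb	0	0
LOH:3-4:10-40Mb	0	0.1318
LOH:3-4:>40Mb	0	0.19771
LOH:5-8:0-100kb	0	0
LOH:5-8:100kb-1Mb	0	0
LOH:5-8:1-10Mb	0	0
LOH:5-8:10-40Mb	0	0
LOH:5-8:>40Mb	0	0
LOH:9+:0-100kb	0	0
LOH:9+:100kb-1Mb	0	0
LOH:9+:1-10Mb	0	0
LOH:9+:10-40Mb	0	0
LOH:9+:>40Mb	0	0
het:2:0-100kb	0	0
het:2:100kb-1Mb	0.08437	0
het:2:1-10Mb	0.31639	0
het:2:10-40Mb	0.58004	0.1318
het:2:>40Mb	0.73823	0.19771
het:3-4:0-100kb	0	0
het:3-4:100kb-1Mb	0	0
het:3-4:1-10Mb	0.05273	0.24164
het:3-4:10-40Mb	0	0.54919
het:3-4:>40Mb	0	0.71394
het:5-8:0-100kb	0	0
het:5-8:100kb-1Mb	0	0
het:5-8:1-10Mb	0	0
het:5-8:10-40Mb	0	0
het:5-8:>40Mb	0	0.1318
het:9+:0-100kb	0	0
het:9+:100kb-1Mb	0	0
het:9+:1-10Mb	0	0
het:9+:10-40Mb	0	0
het:9+:>40Mb	0	0
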