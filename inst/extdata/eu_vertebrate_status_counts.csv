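taxon,status,total,listed
amphibian,CR,2,0
amphibian,EN,5,1
amphibian,VU,11,4
amphibian,NT,15,6
amphibian,LC,49,26
amphibian,NE,2,0
amphibian,DD,1,0
bird,CR,2,1
bird,EN,8,7
bird,VU,15,11
bird,NT,24,21
bird,LC,428,173
bird,NE,0,0
bird,DD,0,0
fish,CR,45,7
fish,EN,38,6
fish,VU,57,6
fish,NT,16,2
fish,LC,172,27
fish,NE,45,0
fish,DD,23,1
mammal,CR,2,2
mammal,EN,5,2
mammal,VU,14,8
mammal,NT,19,14
mammal,LC,125,31
mammal,NE,10,5
mammal,DD,11,3
reptile,CR,6,2
reptile,EN,12,5
reptile,VU,8,3
reptile,NT,18,5
reptile,LC,79,24
reptile,NE,12,1
reptile,DD,3,0
Total,CR,57,12
Total,EN,68,21
Total,VU,105,32
Total,NT,92,48
Total,LC,853,277
Total,NE,69,6
Total,DD,38,4
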