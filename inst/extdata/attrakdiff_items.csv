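group,item,negative,positive
PQ,1,complicated,simple
PQ,2,confusing,clearly structured
PQ,3,cumbersome,straightforward
PQ,4,impractical,practical
PQ,5,technical,human
PQ,6,unpredictable,predictable
PQ,7,unruly,manageable
ATT,1,bad,good
ATT,2,disagreeable,likeable
ATT,3,discouraging,motivating
ATT,4,rejecting,inviting
ATT,5,repelling,appealing
ATT,6,ugly,attractive
ATT,7,unpleasant,pleasant
HQ-I,1,alienating,integrating
HQ-I,2,cheap,premium
HQ-I,3,isolating,connective
HQ-I,4,separates me from people,brings me closer to people
HQ-I,5,tacky,stylish
HQ-I,6,unpresentable,presentable
HQ-I,7,unprofessional,professional
HQ-S,1,cautious,bold
HQ-S,2,conservative,innovative
HQ-S,3,conventional,inventive
HQ-S,4,dull,captivating
HQ-S,5,ordinary,novel
HQ-S,6,undemanding,challenging
HQ-S,7,unimaginative,creative
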