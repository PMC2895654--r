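strain_id	site	lat	lon	mating_type
QS31	Texas - Houston Arboretum	NA	NA	matA1
QS40	Massachusetts - Mt. Greylock	NA	NA	matA2
QS48	North Carolina - Linville Falls	NA	NA	matA2
QS101	Arkansas - Forest City	NA	NA	matA1
QS30	Texas - Carthage	NA	NA	matA3
QS82	Illinois - Effingham	NA	NA	matA3
QS83	Missouri - St. Louis	NA	NA	unknown
QS38	Virginia - Mt. Lake Biological Station	NA	NA	unknown
QS37	Texas - Linden	NA	NA	unknown
QS34	Indiana - Bloomington	NA	NA	matA2
QS36	Kentucky - Land between the Lakes	NA	NA	unknown
QS39	Tennessee - Indian Gap	NA	NA	unknown
QS8	Virginia - Mt. Lake Biological Station	NA	NA	matA2
QS45	Virginia - Mt. Lake Biological Station	NA	NA	matA3
QS49	Virginia - Mt. Lake Biological Station	NA	NA	matA2
QS35	Virginia - Mt. Lake Biological Station	NA	NA	matA3
QS125	Virginia - Mt. Lake Biological Station	NA	NA	matA3
QS135	Virginia - Mt. Lake Biological Station	NA	NA	matA1
QS14	Virginia - Mt. Lake Biological Station	NA	NA	matA2
QS95	Virginia - Mt. Lake Biological Station	NA	NA	matA2
QS131	Virginia - Mt. Lake Biological Station	NA	NA	unknown
QS150	Virginia - Mt. Lake Biological Station	NA	NA	matA3
QS132	Virginia - Mt. Lake Biological Station	NA	NA	matA1
QS136	Virginia - Mt. Lake Biological Station	NA	NA	matA2
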