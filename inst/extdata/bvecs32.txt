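0.48771118 0.74253825 0.43751995 0.88763534 0.20993004 -0.35521399 0.98146122 0.96651716 0.015625998 0.556333 -0.131549 0.088798996 -0.184705 0.60763094 -0.63331913 0.89516691 -0.55632908 0.10466001 0.17511398 -0.23535215 -0.40017911 0.73407018 0.81277884 0.62661474 -0.54425081 0.79436623 -0.22698689 0.34094023 0.8740571 0.19662298 0.77958508 0.48239983
-0.099395038 0.34866312 0.38390496 -0.32332912 0.93860616 0.070244998 -0.052819012 0.10665402 -0.28814297 0.830747 0.49842501 0.70864997 0.97986901 0.65755093 0.70414414 0.39653596 0.82679412 0.14408502 0.95760587 0.82719152 -0.38026811 -0.067873017 0.55127789 -0.62417674 0.47251383 -0.23969807 0.87766559 -0.52941635 -0.47706005 0.72470191 0.20610402 0.73491374
0.86732833 -0.57190119 0.81313792 -0.32796613 0.27376605 0.93214197 0.18423904 -0.23338704 0.9574599 0.018789 0.85689402 -0.69994997 0.075768001 0.44543396 0.32107306 0.20355698 -0.083123012 0.98401514 -0.22874897 0.51025832 0.83381823 -0.67567316 -0.18836996 0.4666448 0.69319675 0.55814616 -0.4221138 0.77683852 0.09185801 0.66041392 0.59141206 -0.47664683
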