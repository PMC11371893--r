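{"vessel_id":"EX001","points":[[0,0,0],[0,0,0.2],[0,0,0.4],[0,0,0.6],[0,0,0.8],[0,0,1],[0,0,1.2],[0,0,1.4],[0,0,1.6],[0,0,1.8],[0,0,2],[0,0,2.2],[0,0,2.4],[0,0,2.6],[0,0,2.8],[0,0,3],[0,0,3.2],[0,0,3.4],[0,0,3.6],[0,0,3.8],[0,0,4],[0,0,4.2],[0,0,4.4],[0,0,4.6],[0,0,4.8],[0,0,5],[0,0,5.2],[0,0,5.4],[0,0,5.6],[0,0,5.8],[0,0,6],[0,0,6.2],[0,0,6.4],[0,0,6.6],[0,0,6.8],[0,0,7],[0,0,7.2],[0,0,7.4],[0,0,7.6],[0,0,7.8],[0,0,8],[0,0,8.2],[0,0,8.4],[0,0,8.6],[0,0,8.8],[0,0,9],[0,0,9.2],[0,0,9.4],[0,0,9.6],[0,0,9.8],[0,0,10],[0,0,10.2],[0,0,10.4],[0,0,10.6],[0,0,10.8],[0,0,11],[0,0,11.2],[0,0,11.4],[0,0,11.6],[0,0,11.8],[0,0,12],[0,0,12.2],[0,0,12.4],[0,0,12.6],[0,0,12.8],[0,0,13],[0,0,13.2],[0,0,13.4],[0,0,13.6],[0,0,13.8],[0,0,14],[0,0,14.2],[0,0,14.4],[0,0,14.6],[0,0,14.8],[0,0,15],[0,0,15.2],[0,0,15.4],[0,0,15.6],[0,0,15.8],[0,0,16],[0,0,16.2],[0,0,16.4],[0,0,16.6],[0,0,16.8],[0,0,17],[0,0,17.2],[0,0,17.4],[0,0,17.6],[0,0,17.8],[0,0,18],[0,0,18.2],[0,0,18.4],[0,0,18.6],[0,0,18.8],[0,0,19],[0,0,19.2],[0,0,19.4],[0,0,19.6],[0,0,19.8],[0,0,20],[0,0,20.2],[0,0,20.4],[0,0,20.6],[0,0,20.8],[0,0,21],[0,0,21.2],[0,0,21.4],[0,0,21.6],[0,0,21.8],[0,0,22],[0,0,22.2],[0,0,22.4],[0,0,22.6],[0,0,22.8],[0,0,23],[0,0,23.2],[0,0,23.4],[0,0,23.6],[0,0,23.8],[0,0,24],[0,0,24.2],[0,0,24.4],[0,0,24.6],[0,0,24.8],[0,0,25],[0,0,25.2],[0,0,25.4],[0,0,25.6],[0,0,25.8],[0,0,26],[0,0,26.2],[0,0,26.4],[0,0,26.6],[0,0,26.8],[0,0,27],[0,0,27.2],[0,0,27.4],[0,0,27.6],[0,0,27.8],[0,0,28],[0,0,28.2],[0,0,28.4],[0,0,28.6],[0,0,28.8],[0,0,29],[0,0,29.2],[0,0,29.4],[0,0,29.6],[0,0,29.8]],"areas":[6.625446,6.614501,6.603565,6.592639,6.581721,6.570812,6.559912,6.549022,6.53814,6.527267,6.516404,6.505549,6.494704,6.483868,6.47304,6.462222,6.451413,6.440612,6.429821,6.419039,6.408266,6.397502,6.386747,6.376001,6.365264,6.354537,6.343818,6.333108,6.322407,6.311716,6.301033,6.29036,6.279695,6.26904,6.258393,6.247756,6.237128,6.226509,6.215898,6.205297,6.110462,5.932142,5.754854,5.578708,5.403915,5.230778,5.059684,4.891086,4.725486,4.563418,4.405421,4.252029,4.103748,3.961049,3.824353,3.694026,3.570381,3.453674,3.344107,3.241839,3.146983,3.059622,2.97981,2.907582,2.842959,2.78595,2.736559,2.694786,2.660628,2.63408,2.615134,2.60378,2.6,2.601765,2.607052,2.615845,2.628126,2.643873,2.663055,2.685637,2.711572,2.740804,2.773265,2.808874,2.847541,2.889161,2.933619,2.980791,3.030544,3.082741,3.13724,3.1939,3.252584,3.313162,3.375511,3.439523,3.505104,3.572178,3.640683,3.710577,3.781833,3.854438,3.92839,4.003693,4.08035,4.158364,4.237724,4.318403,4.400353,4.483496,4.567724,4.652894,4.738827,4.825307,4.912086,4.998889,5.085417,5.171357,5.256394,5.340219,5.376652,5.366793,5.356943,5.347101,5.337269,5.327446,5.317632,5.307827,5.298032,5.288245,5.278467,5.268698,5.258938,5.249188,5.239446,5.229714,5.21999,5.210276,5.20057,5.190874,5.181187,5.171508,5.161839,5.152179,5.142528,5.132886,5.123253,5.113629,5.104014,5.094408]}
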