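"swimmer_id","session","sex","age_y","height_cm","sitting_height_cm","arm_span_cm","body_mass_kg","breast_t25_s","breast_t10_s","breast_t3cycles_s","fly_t25_s","fly_t10_s","fly_t3cycles_s"
"S001","before","F",10.6768,139.1119,73.327,131.5646,35.5399,48.5226,17.503,2.9814,23.9705,9.0652,4.4221
"S002","before","F",8.5964,140.7026,73.9282,151.6912,38.0721,26.3648,11.2225,4.4974,23.252,8.7434,4.6602
"S003","before","F",10.181,128.7973,69.3271,131.0761,35.0699,41.1414,17.5027,4.1677,30.606,12.4741,3.9713
"S004","before","F",9.8898,156.5185,79.8093,146.7898,34.3121,46.9347,19.1138,5.5094,29.1887,10.8525,7.3019
"S005","before","F",9.1334,142.7676,72.9567,134.93,22.4779,39.3207,14.2173,3.1169,57.2219,22.3705,3.724
"S006","before","F",6.7291,160.8084,85.3954,158.3487,34.4636,33.7781,12.3167,3.423,28.5063,11.8428,6.3645
"S007","before","F",9.0443,159.0902,84.1628,151.0026,21.9406,35.4807,14.111,6.597,40.8832,15.1045,4.461
"S008","before","F",8.6738,142.864,76.6656,139.414,46.1525,42.5216,16.1613,2.8335,35.9761,13.6944,4.0335
"S009","before","F",10.1476,148.5597,77.2257,151.9134,28.4728,31.8039,11.7496,5.6274,29.4241,11.6362,4.5685
"S010","before","F",9.3841,159.0386,84.1434,148.0354,37.9153,26.8938,10.0027,5.3923,28.1303,10.5708,8.1933
"S011","before","F",9.4693,137.169,73.6396,131.4331,40.9599,56.7356,21.0536,6.3414,31.6759,13.3034,4.8211
"S012","before","M",9.8426,143.914,73.3126,141.4555,36.7446,29.892,11.2761,5.6786,23.465,8.0974,4.4614
"S013","before","M",10.3007,139.8292,76.4078,133.9217,47.7456,40.8546,15.3136,4.3104,26.733,11.5471,3.8546
"S014","before","M",10.2968,145.528,74.081,148.2737,29.7543,29.4291,12.0811,3.4456,36.8717,13.8203,4.2905
"S015","before","M",8.2078,144.0696,71.3847,136.894,40.3359,59.1059,20.3634,4.8078,30.9136,11.9121,4.2159
"S016","before","M",11.7123,153.5966,79.5845,141.1932,28.6874,38.3182,14.7335,4.1349,33.2911,13.4779,3.7357
"S017","before","M",11.0548,148.0569,77.4429,130.7418,54.1208,45.2078,16.8085,4.2302,47.3798,17.7561,5.9528
"S018","before","M",10.6958,133.6497,68.1281,133.6061,42.3391,37.5685,15.3571,3.0083,30.2332,11.7566,5.7878
"S019","before","M",9.7758,147.8994,74.6529,144.9931,33.8844,44.3767,17.2199,2.4612,30.3502,10.7427,4.8623
"S020","before","M",11.1208,134.2984,68.4826,133.2099,43.1384,36.1147,13.2568,5.4249,29.9215,12.0641,4.4568
"S001","after","F",11.5265,145.7119,76.806,140.3889,42.8414,31.2402,11.2689,1.6195,15.0388,5.6874,2.6888
"S002","after","F",9.4636,145.2045,76.2936,153.5095,41.0022,20.1048,8.5578,2.8154,17.3007,6.5055,4.2908
"S003","after","F",11.0675,131.8805,70.9867,135.6144,40.3883,41.5645,17.6827,12.8665,25.1357,10.2445,4.0485
"S004","after","F",10.8923,160.2435,81.7087,154.1835,41.3536,34.491,14.0462,3.7861,16.8544,6.2665,4.7335
"S005","after","F",9.9348,146.8499,75.0428,140.691,24.5699,32.9704,11.9212,2.3084,44.9927,17.5896,2.9795
"S006","after","F",7.358,169.5741,90.0503,168.0532,37.9653,33.5427,12.2309,3.1574,21.8176,9.064,5.0637
"S007","after","F",10.0083,165.1747,87.3817,158.6796,25.3471,25.7874,10.2558,6.4216,29.7392,10.9873,3.1429
"S008","after","F",9.4803,146.1099,78.4074,144.2248,46.5331,26.2317,9.97,4.3802,21.0011,7.9941,3.897
"S009","after","F",11.0505,152.5548,79.3024,159.2178,33.0912,22.7013,8.3867,3.5193,19.6614,7.7754,4.0274
"S010","after","F",10.1015,167.4225,88.5791,156.2782,40.3242,25.3636,9.4335,5.0077,18.0909,6.7982,6.1813
"S011","after","F",10.3458,140.1833,75.2578,137.1384,43.9655,43.1647,16.0177,3.8682,29.804,12.5172,6.6568
"S012","after","M",10.6174,149.3465,76.08,148.1875,41.3831,26.6969,10.0708,7.2436,17.6892,6.1042,4.1643
"S013","after","M",11.5053,145.3292,79.4133,142.7646,54.0527,29.8381,11.1843,2.1603,15.0203,6.4879,3.5878
"S014","after","M",11.2153,149.4947,76.1002,155.5953,32.1972,20.5349,8.4299,2.5676,21.9824,8.2395,4.6772
"S015","after","M",8.8292,148.8482,73.7524,143.0297,49.3585,40.8759,14.0827,3.8209,27.9903,10.7857,4.2046
"S016","after","M",12.9759,160.8299,83.3324,149.7379,30.9084,24.925,9.5837,2.3484,31.6616,12.8182,3.0372
"S017","after","M",11.8837,151.383,79.1827,131.2552,54.2304,40.1156,14.9151,6.8669,46.5782,17.4557,6.3712
"S018","after","M",11.4029,140.7175,71.7309,141.8139,52.3375,33.2328,13.5848,2.5915,24.1317,9.3839,5.9816
"S019","after","M",10.5217,157.6404,79.5697,155.4249,39.5941,32.2449,12.5123,1.5407,17.1585,6.0734,3.4107
"S020","after","M",12.0827,142.5388,72.6846,143.0408,46.3822,37.5481,13.6161,4.5806,19.2573,7.7644,3.6022
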