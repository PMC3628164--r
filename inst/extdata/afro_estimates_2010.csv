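unit_id,total_pop_thousands,cbr,n_surveys,af_median,af_q25,af_q75,ac_median,ac_q25,ac_q75,cc_median,cc_q25,cc_q75,reference_cc
Algeria,35423,0.0192,15,0.003,0.002,0.005,3439,1839,7119,46,15,159,72
Angola,18994,0.0399,1,0.001,0.000,0.006,1510,257,9539,4,0,102,0
Benin,9219,0.0383,9,0.064,0.046,0.090,41915,32952,52400,1892,1188,3200,746
Botswana,1977,0.0229,0,0.000,0.000,0.000,0,0,11,0,0,0,0
Burkina Faso,16250,0.0424,42,0.130,0.108,0.158,131454,117825,146173,9592,7258,13259,3730
Burundi,8519,0.0333,1,0.000,0.000,0.002,132,31,578,0,0,1,0
Cameroon,19957,0.0349,11,0.001,0.000,0.001,400,146,1127,0,0,3,5
Cape Verde,513,0.0199,2,0.000,0.000,0.001,1,0,10,0,0,0,0
Central African Republic,4506,0.0345,0,0.000,0.000,0.001,27,4,187,0,0,0,0
Chad,11509,0.0434,5,0.002,0.001,0.004,1282,390,4183,7,1,58,6
Comoros,691,0.0357,0,0.000,0.000,0.000,0,0,1,0,0,0,0
Congo,3760,0.0346,1,0.001,0.000,0.003,112,21,898,0,0,6,0
"Congo, the Democratic Republic of the",67829,0.0421,4,0.001,0.000,0.001,1813,594,6213,2,0,30,0
Côte d'Ivoire,21571,0.0330,3,0.028,0.017,0.049,42277,27050,64339,1244,576,2922,935
Equatorial Guinea,693,0.0359,0,0.001,0.000,0.004,38,10,177,0,0,1,0
Eritrea,5204,0.0344,0,0.000,0.000,0.002,20,1,379,0,0,1,0
Ethiopia,84996,0.0300,1,0.000,0.000,0.002,470,36,6754,0,0,21,0
Gabon,1501,0.0270,1,0.004,0.001,0.009,299,81,838,1,0,9,0
Gambia,1751,0.0369,12,0.005,0.003,0.008,609,302,1138,2,1,9,8
Ghana,24339,0.0303,18,0.074,0.061,0.090,98153,87225,110939,4707,3601,6546,2501
Guinea,10324,0.0376,1,0.013,0.007,0.023,11186,5931,19970,162,49,497,0
Guinea-Bissau,1647,0.0374,1,0.003,0.001,0.006,303,108,815,1,0,6,1
Kenya,40835,0.0369,1,0.001,0.000,0.003,1048,170,7501,1,0,29,0
Lesotho,2064,0.0271,0,0.000,0.000,0.000,0,0,2,0,0,0,0
Liberia,4102,0.0376,12,0.004,0.002,0.007,1275,620,2476,6,2,21,4
Madagascar,20146,0.0346,0,0.000,0.000,0.000,0,0,11,0,0,0,0
Malawi,15690,0.0445,0,0.000,0.000,0.000,4,0,97,0,0,0,0
Mali,13362,0.0450,7,0.078,0.049,0.128,79506,58011,106112,4354,2257,9952,1616
Mauritania,3359,0.0327,1,0.023,0.009,0.066,5309,2136,11459,145,24,808,18
Mauritius,1297,0.0125,0,0.000,0.000,0.000,0,0,0,0,0,0,0
Mozambique,23418,0.0363,0,0.000,0.000,0.000,2,0,68,0,0,0,0
Namibia,2212,0.0252,0,0.001,0.000,0.003,32,3,378,0,0,2,0
Niger,15885,0.0477,3,0.025,0.015,0.049,40670,24006,69159,1196,527,3068,734
Nigeria,158255,0.0393,16,0.011,0.008,0.015,148423,112961,197818,3099,1822,5948,3278
Rwanda,10277,0.0406,1,0.001,0.000,0.002,446,129,1554,0,0,3,0
Sao Tome and Principe,165,0.0299,0,0.004,0.001,0.026,36,3,305,0,0,6,1
Senegal,12866,0.0359,3,0.007,0.004,0.014,7326,3508,14548,56,13,230,64
Sierra Leone,5837,0.0365,0,0.009,0.004,0.022,4508,1575,11076,40,6,228,64
South Africa,50523,0.0205,1,0.000,0.000,0.000,1,0,61,0,0,0,0
Swaziland,1195,0.0287,0,0.000,0.000,0.000,0,0,1,0,0,0,0
"Tanzania, United Republic of",45028,0.0410,13,0.000,0.000,0.001,558,123,3033,0,0,8,0
Togo,6774,0.0310,3,0.082,0.059,0.112,29093,23448,35050,1594,989,2702,446
Uganda,33798,0.0439,1,0.001,0.000,0.004,2721,618,12531,4,0,69,0
Zambia,13254,0.0465,2,0.000,0.000,0.000,23,1,221,0,0,0,0
Zimbabwe,12645,0.0287,0,0.000,0.000,0.000,2,0,40,0,0,0,0
AFRO region,888817,0.0357,198,0.011,0.011,0.012,672117,642116,705163,28703,26027,31958,14227
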