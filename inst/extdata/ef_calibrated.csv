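item_key,category,value,gsd
additive,CC,2.1,1.1
additive,LU,54.78,1.1
additive,WU,9.35,1.1
additive,RU,52.21,1.1
additive,FEU,0.35,1.1
additive,MEU,4.6,1.1
additive,TEU,0.06,1.1
additive,TFWAC,0,1.1
compound_feed_french,CC,1.16378706422523,1.2
roughage_french,CC,0.129309673802803,1.2
luc_french,CC,0.15697592959317,1.2
energy_french,CC,0.136209637996921,1.1
water_french,CC,0.972925985692291,1.1
fuel_french,CC,0.0810771654743576,1.1
compound_feed_french,LU,145.034769812993,1.2
roughage_french,LU,16.1149744236659,1.2
luc_french,LU,19.5628294166363,1.2
energy_french,LU,16.9748694589127,1.1
water_french,LU,121.249067563662,1.1
compound_feed_french,WU,0.716401584761761,1.2
roughage_french,WU,0.0796001760846401,1.2
luc_french,WU,0.0966309114329817,1.2
energy_french,WU,0.0838476414805165,1.1
water_french,WU,0.598911724860832,1.1
compound_feed_french,RU,8.04124227793814,1.2
roughage_french,RU,0.893471364215348,1.2
luc_french,RU,1.08463267934979,1.2
energy_french,RU,0.941146996209879,1.1
water_french,RU,6.72247854435628,1.1
compound_feed_french,TFWAC,0.0403936476321827,1.2
roughage_french,TFWAC,0.00448818307024253,1.2
luc_french,TFWAC,0.00544844549457348,1.2
energy_french,TFWAC,0.00472767251887067,1.1
water_french,TFWAC,0.0337690894205048,1.1
compound_feed_french,FEU,0.307029250612183,1.2
roughage_french,FEU,0.0341143611791315,1.2
luc_french,FEU,0.0414132477569922,1.2
energy_french,FEU,0.0359347034916499,1.1
water_french,FEU,0.256676453511785,1.1
compound_feed_french,MEU,21.3071596569803,1.2
roughage_french,MEU,2.36746218410892,1.2
luc_french,MEU,2.87398897698803,1.2
energy_french,MEU,2.49378996625297,1.1
water_french,MEU,17.8127854732355,1.1
compound_feed_french,TEU,0.182915566019055,1.2
roughage_french,TEU,0.020323951779895,1.2
luc_french,TEU,0.0246723321607097,1.2
energy_french,TEU,0.0214084378468702,1.1
water_french,TEU,0.15291741319193,1.1
compound_feed_uk,CC,2.0175606732757,1.2
roughage_uk,CC,0.0068800022959103,1.2
luc_uk,CC,0.452016150841307,1.2
energy_uk,CC,0.628434545713498,1.1
water_uk,CC,0.910774703932606,1.1
fuel_uk,CC,0,1.1
compound_feed_uk,LU,157.097345988186,1.2
roughage_uk,LU,0.535711324767898,1.2
luc_uk,LU,35.1962340372509,1.2
energy_uk,LU,48.9330509692143,1.1
water_uk,LU,70.9174651727743,1.1
compound_feed_uk,WU,0.775984874336806,1.2
roughage_uk,WU,0.00264615472919627,1.2
luc_uk,WU,0.173852365708195,1.2
energy_uk,WU,0.241705594505192,1.1
water_uk,WU,0.350297963051002,1.1
compound_feed_uk,RU,8.71003430378048,1.2
roughage_uk,RU,0.0297017367562847,1.2
luc_uk,RU,1.9514041048879,1.2
energy_uk,RU,2.71302197913991,1.1
water_uk,RU,3.93191591179696,1.1
compound_feed_uk,TFWAC,0.0482566496853726,1.2
roughage_uk,TFWAC,0.000164558055193087,1.2
luc_uk,TFWAC,0.0108114642261858,1.2
energy_uk,TFWAC,0.015031094789058,1.1
water_uk,TFWAC,0.0217841953464608,1.1
compound_feed_uk,FEU,0.332564946144346,1.2
roughage_uk,FEU,0.00113406631251269,1.2
luc_uk,FEU,0.0745081567320836,1.2
energy_uk,FEU,0.103588111930796,1.1
water_uk,FEU,0.15012769845043,1.1
compound_feed_uk,MEU,24.3073360892816,1.2
roughage_uk,MEU,0.0828894666301162,1.2
luc_uk,MEU,5.44583795759864,1.2
energy_uk,MEU,7.5713062388214,1.1
water_uk,MEU,10.9729075924948,1.1
compound_feed_uk,TEU,0.217514420996382,1.2
roughage_uk,TEU,0.000741737155997892,1.2
luc_uk,TEU,0.0487321311490615,1.2
energy_uk,TEU,0.0677519036505907,1.1
water_uk,TEU,0.0981911647110009,1.1
compound_feed_german,CC,1.40468719720324,1.2
roughage_german,CC,0.05351189322679,1.2
luc_german,CC,0.048160703904111,1.2
energy_german,CC,0.789553001231183,1.1
water_german,CC,0.657960834359319,1.1
fuel_german,CC,0,1.1
compound_feed_german,LU,157.630056518734,1.2
roughage_german,LU,6.00495453404702,1.2
luc_german,LU,5.40445908064232,1.2
energy_german,LU,88.6014227625943,1.1
water_german,LU,73.8345189688285,1.1
compound_feed_german,WU,0.778616206594554,1.2
roughage_german,WU,0.0296615697750307,1.2
luc_german,WU,0.0266954127975276,1.2
energy_german,WU,0.43764815679104,1.1
water_german,WU,0.364706797325867,1.1
compound_feed_german,RU,8.73956966585724,1.2
roughage_german,RU,0.332935987270752,1.2
luc_german,RU,0.299642388543677,1.2
energy_german,RU,4.91237727010351,1.1
water_german,RU,4.09364772508626,1.1
compound_feed_german,TFWAC,0.0455153920773479,1.2
roughage_german,TFWAC,0.00173391969818468,1.2
luc_german,TFWAC,0.00156052772836621,1.2
energy_german,TFWAC,0.0255834996491995,1.1
water_german,TFWAC,0.0213195830409996,1.1
compound_feed_german,FEU,0.333692659969095,1.2
roughage_german,FEU,0.012712101332156,1.2
luc_german,FEU,0.0114408911989404,1.2
energy_german,FEU,0.187563495767589,1.1
water_german,FEU,0.156302913139657,1.1
compound_feed_german,MEU,23.5976203369656,1.2
roughage_german,MEU,0.898956965217739,1.2
luc_german,MEU,0.809061268695965,1.2
energy_german,MEU,13.2638583138375,1.1
water_german,MEU,11.0532152615312,1.1
compound_feed_german,TEU,0.205747493183259,1.2
roughage_german,TEU,0.00783799974031463,1.2
luc_german,TEU,0.00705419976628317,1.2
energy_german,TEU,0.115647491528415,1.1
water_german,TEU,0.0963729096070126,1.1
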