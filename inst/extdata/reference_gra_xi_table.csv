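item,y2015,y2016,y2017,y2018,y2019,y2020,y2021,y2022,y2023,y2024,y2025,gamma_printed,rank_printed
comprehensive_service,0.7164,0.7245,0.7890,0.7605,0.7789,0.7609,0.6902,0.6270,0.7020,0.7802,0.7178,0.7316,3
diagnosis,0.8526,0.8418,0.9239,0.9603,1.0000,0.9760,0.8236,0.7406,0.7471,0.8659,0.9444,0.8797,1
treatment,0.6294,0.6459,0.7096,0.6995,0.7131,0.6893,0.6403,0.5958,0.6894,0.7657,0.7535,0.6847,4
drug,0.7794,0.7938,0.8540,0.8584,0.8724,0.7976,0.6892,0.6206,0.6873,0.7411,0.7177,0.7647,2
blood_products,0.6211,0.6347,0.6988,0.6910,0.7132,0.6910,0.6371,0.5746,0.6111,0.6768,0.6660,0.6559,7
material,0.6231,0.6343,0.6982,0.6937,0.7147,0.6892,0.6448,0.5900,0.6658,0.7021,0.6987,0.6686,6
other,0.6255,0.6375,0.6994,0.6896,0.7123,0.7167,0.7568,0.7067,0.6081,0.6777,0.6738,0.6822,5
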