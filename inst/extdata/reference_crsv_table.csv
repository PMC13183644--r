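period,comprehensive_service,diagnosis,treatment,drug,blood_products,material,other
2015-2016,7.29,42.71,21.23,7.91,11.70,3.06,6.10
2016-2017,8.09,48.25,3.66,26.76,1.36,0.39,11.48
2017-2018,30.68,37.80,7.56,10.89,4.21,1.32,7.55
2018-2019,8.04,34.59,24.76,17.20,5.93,1.63,7.85
2019-2020,7.84,0.42,0.70,48.30,2.88,1.70,38.15
2020-2021,5.25,25.03,3.58,19.72,1.20,5.87,39.35
2021-2022,4.74,22.88,26.44,13.95,8.43,7.17,16.39
2022-2023,10.83,7.95,17.74,8.72,0.10,12.71,41.95
2023-2024,6.78,34.81,5.59,15.01,1.73,33.25,2.82
2024-2025,36.30,41.21,1.95,10.17,1.58,4.49,4.30
2015-2025,15.55,9.25,28.11,34.06,0.39,11.66,0.99
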