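period,comprehensive_service,diagnosis,treatment,drug,blood_products,material,other,dsv_printed
2015-2016,-0.0051,-0.0298,0.0148,0.0055,0.0082,0.0021,0.0043,6.98
2016-2017,-0.0034,0.0203,-0.0015,-0.0113,0.0006,0.0002,-0.0048,4.20
2017-2018,-0.0443,0.0546,-0.0109,0.0157,-0.0061,0.0019,-0.0109,14.44
2018-2019,-0.0053,0.0230,-0.0165,-0.0114,0.0039,0.0011,0.0052,6.65
2019-2020,0.0136,0.0007,0.0012,-0.0836,0.0050,-0.0029,0.0660,17.31
2020-2021,-0.0258,-0.1226,0.0176,-0.0966,0.0059,0.0288,0.1928,49.01
2021-2022,-0.0061,-0.0296,0.0342,-0.0181,-0.0109,0.0093,0.0212,12.95
2022-2023,0.0739,-0.0543,0.1211,0.0595,-0.0006,0.0868,-0.2863,68.25
2023-2024,0.0145,0.0744,0.0119,-0.0321,-0.0037,-0.0711,0.0060,21.37
2024-2025,-0.1040,0.1181,-0.0056,-0.0291,-0.0045,0.0129,0.0123,28.65
2015-2025,-0.0920,0.0547,0.1663,-0.2015,-0.0023,0.0690,0.0059,59.17
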