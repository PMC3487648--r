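subject,scope,tabular,citation
"Anthemiphyllia, species",comprehensive,TRUE,[Bibr B16]: 290)
"Asterosmilia, species",comprehensive,TRUE,[Bibr B23]: 38)
"Aulocyathus, species",comprehensive,FALSE,[Bibr B16]: 104)
"Caryophyllia, species",comprehensive,TRUE,[Bibr B11]: 12)
"Caryophyllia, species",comprehensive,FALSE,[Bibr B35]: 112)
"Conocyathus, species",comprehensive,FALSE,[Bibr B9]: 290)
"Crispatotrochus, species",comprehensive,FALSE,[Bibr B32]: 62)
"Deltocyathus, species",comprehensive,FALSE,[Bibr B33]: 236)
"Dendrophylliidae, genera",comprehensive,TRUE,[Bibr B18]: 5)
"Flabellidae, genera",comprehensive,TRUE,[Bibr B57]: 26); [Bibr B9]: 45)
"Guyniidae, genera",comprehensive,TRUE,[Bibr B9]: 41); [Bibr B51]: 23)
"Javania, species",comprehensive,FALSE,[Bibr B20]: 10)
"Micrabaciidae, genera",comprehensive,FALSE,[Bibr B9]: 13)
"Placotrochides, species",comprehensive,FALSE,[Bibr B19]: 307)
"Scleractinia, families and genera",comprehensive,FALSE,[Bibr B54]
"Stephanophyllia, species",comprehensive,FALSE,[Bibr B9]: 21)
"Trochocyathus (Aplocyathus), species",comprehensive,TRUE,[Bibr B16]: 85)
"Turbinoliidae, genera",comprehensive,TRUE,[Bibr B7]: 711; [Bibr B9]: 25; [Bibr B23]: 5 [T]); [Bibr B28]: 44)
"Astrangia, E. Pacific",faunistic,FALSE,[Bibr B27]: 60)
"Azooxanthellate Scleractinia, Antarctica",faunistic,FALSE,[Bibr B1]: 18 [book])
"Azooxanthellate Scleractinia, E. Gulf of Mexico",faunistic,FALSE,[Bibr B2]: 5)
"Azooxanthellate Scleractinia, New Zealand",faunistic,FALSE,[Bibr B49]: 13); [Bibr B53]
"Azooxanthellate Scleractinia, NE Pacific",faunistic,FALSE,[Bibr B12]: 13)
"Azooxanthellate Scleractinia, NW Pacific",faunistic,FALSE,[Bibr B12]: 75)
"Azooxanthellate Scleractinia, S. Australia",faunistic,FALSE,[Bibr B22]: 4)
"Azooxanthellate Scleractinia, Cold Temp. NE Atl.",faunistic,FALSE,[Bibr B6]: 3)
"Azooxanthellate Scleractinia, Brazil",faunistic,FALSE,[Bibr B31]: 510)
"Balanophyllia, W. Atlantic",faunistic,FALSE,[Bibr B3]: 133)
"Balanophyllia, Japan",faunistic,FALSE,[Bibr B42]: 145 [in Japanese])
"Balanophyllia, W. Atlantic",faunistic,TRUE,[Bibr B17]: 163)
"Caryophyllia, New Zealand",faunistic,FALSE,[Bibr B13]: 43)
"Caryophyllia, W. Atlantic",faunistic,FALSE,[Bibr B5]: 46)
"Caryophyllia, W. Pacific",faunistic,FALSE,"[Bibr B24]: 87, 96)"
"Caryophyllia and Premocyathus, Japan",faunistic,FALSE,[Bibr B43]: 115 [in Japanese])
"Conotrochus and Trochocyathus, Japan",faunistic,FALSE,[Bibr B46]: 57 [in Japanese])
"Culicia, Australia",faunistic,FALSE,[Bibr B19]: 274)
"Deltocyathus, W. Atlantic",faunistic,FALSE,[Bibr B5]: 91)
"Deltocyathus, W. Pacific",faunistic,FALSE,[Bibr B24]: 121)
"Dendrophyllia, Japan",faunistic,FALSE,[Bibr B38]: 25 [in Japanese])
"Flabellum, New Zealand",faunistic,FALSE,[Bibr B13]: 96)
"Flabellum, Japan",faunistic,FALSE,[Bibr B40]: 56 [in Japanese])
"Fungiacyathus, W. Pacific",faunistic,TRUE,"[Bibr B9]: 6, 7; [Bibr B16]: 55)"
"Fungiacyathus, Japan",faunistic,FALSE,[Bibr B39]: 11 [in Japanese])
"Heterocyathus, W. Pacific",faunistic,FALSE,[Bibr B29]: 222)
"Heterocyathus, Japan",faunistic,FALSE,[Bibr B41]: 248 [in Japanese])
"Heteropsammia, W. Pacific",faunistic,FALSE,[Bibr B29]: 222)
"Heteropsammia, Japan",faunistic,FALSE,[Bibr B41]: 248 [in Japanese])
"Madracis, W. Atlantic",faunistic,FALSE,[Bibr B56]: 19)
"Paracyathus and Polycyathus, Japan",faunistic,FALSE,[Bibr B44]: 55 [in Japanese])
"Trochocyathus, W. Pacific",faunistic,FALSE,[Bibr B24]: 105)
"Truncatoflabellum, W, Pacific",faunistic,FALSE,[Bibr B9]: 62)
"Truncatoflabellum, SW Indian Ocean",faunistic,FALSE,[Bibr B21]: 264)
"Truncatoflabellum, Australia",faunistic,TRUE,[Bibr B15]: 397)
"Truncatoflabellum, Japan",faunistic,FALSE,[Bibr B36]: 13 [in Japanese])
"Tubastraea, Red Sea",faunistic,FALSE,[Bibr B48]: 173)
"Tubastraea, Galapagos",faunistic,FALSE,[Bibr B11]: 27)
"Tubastraea, Japan",faunistic,FALSE,[Bibr B37]: 97 [in Japanese])
"Turbinoliidae, Japan",faunistic,FALSE,[Bibr B45]: 27 [in Japanese])
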