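IF HQKNDSANTVITTWLTRGSC>=5.265 THEN type = "Sarcoma"
IF MNVHYAAQDVINFGAHQGSC>=1.497 AND RENQHEIGVALARSHKMGSC<=0.427 THEN type = "Glioblastoma multiformae"
IF ELIAFRDFNWRGGVVAGGSC>=2.837 AND KWKQDYINNHFVKVNRTGSC>=1.622 THEN type = "Glioblastoma multiformae"
IF VWGKGGMYEAHYRRNGEGSC>=2.360 AND DEPKQYASWYTHWTNWAGSC>=3.931 THEN type = "Glioblastoma multiformae"
IF HDWNVAWELRRWKALIYGSC>=1.791 AND GTQPMVAWKDVYGIVVYGSC>=1.510 AND AAVAKRIAEQHMWMQVGGSC>=0.683 THEN type = "Breast cancer stage IVa"
IF KFPNEFRYRYNWRMQNPGSC>=7.729 AND AAVPKYINAMWKGYAPDGSC<=0.609 THEN type = "Breast cancer stage IVa"
IF FHWNMYKNSESLFEEKQGSC>=2.110 THEN type = "Oligodendroglioma"
IF PGLTHNTLQYMATVLSVGSC>=1.876 AND AAKFRTQWMHWMIWHHTGSC>=0.752 THEN type = "Oligodendroglioma"
IF PGLTHNTLQYMATVLSVGSC>=1.876 AND AAKFRTQWMHWMIWHHTGSC>=0.752 THEN type = "Oligodendroglioma"
IF QVNKAVSWYLVWHLWHQGSC>=1.183 AND AGLLWQWKGWDYIHEWNGSC<=0.466 AND LWFGTMPWHSIRAHDVHGSC<=0.616 THEN type = "Recurrent breast cancer"
IF HYNRYMVIIGNWGKQPIGSC<=0.509 AND GNSVRAFITVLMQIFFTGSC>=1.727 AND MKPLISYGPAWFGPLLWGSC>=0.538 THEN type = "Recurrent breast cancer"
IF GDQHQLEPPYKKNQYMIGSC>=1.857 AND RTGAGHTWDSTGHIQKVGSC>=0.968 THEN type = "Recurrent breast cancer"
IF RQNTIRSRQKINLGGGDGSC>=1.853 AND AADTGGFDLIWNEVKGHGSC>=1.130 THEN type = "Recurrent breast cancer"
IF PVGEVSSDYNRGPWRGTGSC>=1.977 THEN type = "Recurrent breast cancer"
IF SWIHGWLTITIYGFKERGSC>=1.631 AND AAVAKRIAEQHMWMQVGGSC<=0.331 THEN type = "Recurrent breast cancer"
IF DLVMPTNHESLSQLTGDGSC>=1.004 AND PFPNYPIYPMWMMHEREGSC>=2.888 THEN type = "Pancreatitis"
IF LERGHRADMAYRDTFPMGSC>=2.128 AND DQYELTQDLHVVKSYFAGSC<=0.512 THEN type = "Pancreatitis"
IF IKSRTGAEEIQIQMLLRGSC>=2.858 THEN type = "Pancreatitis"
IF LSERWAMGAHRDTASQTGSC>=1.540 AND ADDHEQWTEKMYKNQNMGSC>=0.523 THEN type = "Ovarian cancer"
IF ADVKMLWEWNDVKVLIIGSC>=4.318 THEN type = "Ovarian cancer"
IF VNFESFREPTFGSDGYSGSC>=2.353 AND EWYYDPRGGTGSFYMRTGSC>=0.972 THEN type = "Mixed Oligo/Astrocytoma"
IF LIVFTKGHRMYNDIPTNGSC<=0.434 AND APYTPQFFEAQTWWINGGSC>=1.146 THEN type = "Mixed Oligo/Astrocytoma"
IF YLSTSMEQEQEQVHGNWGSC>=2.247 AND ILDRRETAWNEHFSKFRGSC>=1.236 THEN type = "Mixed Oligo/Astrocytoma"
IF TVKKMYNGGLASKNALYGSC<=0.171 AND GHAVQGGLKRAHRVYKQGSC>=1.766 THEN type = "Mixed Oligo/Astrocytoma"
IF TQGVAHFGQTHYPYQLEGSC>=1.942 AND PHEEYMRQFHSAGQPTFGSC>=1.416 AND HHAFFNGEYMKMMSLSIGSC>=0.051 THEN type = "Lung cancer"
IF YVQEHAQWKNMWELANGGSC>=2.325 AND AADTGGFDLIWNEVKGHGSC<=0.806 THEN type = "Lung cancer"
IF FLKFMQKMSTVHIIWLNGSC<=0.118 AND ANQTHYDPTSSDMVWPKGSC>=1.071 THEN type = "Lung cancer"
IF TAKWYGIRNSQDEKVEAGSC>=1.756 AND AAKFRTQWMHWMIWHHTGSC>=0.750 THEN type = "Lung cancer"
IF YINSYPIAKPHGEEMQMGSC<=0.461 AND ETDKTINVREAAAHGMKGSC<=0.390 THEN type = "Multiple myeloma"
IF ERIYRDHFIHEHKANIIGSC<=0.545 AND NLFRWLWNRRHVWDQDRGSC>=1.092 THEN type = "Multiple myeloma"
IF TAHGKARDFDPAKNRYLGSC<=0.398 THEN type = "Multiple myeloma"
IF HFGIVISVMNEKEGALRGSC>=7.715 THEN type = "Multiple myeloma"
IF YFMWPFWWYSHVWGRDWGSC>=1.001 AND IITIWLDGGLMHDFEKPGSC>=1.028 AND AEMGFTSPERDQGASQEGSC<=1.493 THEN type = "Pancreatic cancer"
IF WWWFHSLGLLAHIKIALGSC>=1.122 AND FGFDFGDLWIIPDAIAMGSC>=1.068 THEN type = "Pancreatic cancer"
IF IISNTTMAVLWMLQSSRGSC>=1.429 AND ANQTHYDPTSSDMVWPKGSC>=0.758 THEN type = "Pancreatic cancer"
IF TYQRRMGGVRGQQPYNKGSC>=2.089 AND DGDPTAITNWWWETGNWGSC<=0.728 THEN type = "Breast cancer"
IF PKQHGRQQNQGIFKPMLGSC>=2.538 AND AGGNHLAIAFNAIFLNMGSC<=0.717 THEN type = "Breast cancer"
IF FKETAMPVLNYPVGVNEGSC>=1.959 THEN type = "Healthy normal donor"
IF GEASDNYKWWWDHVVYPGSC>=1.854 THEN type = "Astrocytoma"
IF FFYKKDFTPRHTFQNRRGSC<=0.529 AND AEMGFTSPERDQGASQEGSC<=0.586 THEN type = "Astrocytoma"
IF APMKNIVSAKTKDFAYMGSC<=0.324 THEN type = "Astrocytoma"
IF Others THEN type = "Healthy normal donor"
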