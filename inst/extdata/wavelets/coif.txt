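coif1	lo	-7.2732619512526450e-02 3.3789766245748182e-01 8.5257202021160039e-01 3.8486484686485778e-01 -7.2732619512526450e-02 -1.5655728135791993e-02
coif2	lo	1.6387336463203641e-02 -4.1464936786871777e-02 -6.7372554723725595e-02 3.8611006682276289e-01 8.1272363544941351e-01 4.1700518442323908e-01 -7.6488599078280761e-02 -5.9434418646431092e-02 2.3680171946847770e-02 5.6114348193688343e-03 -1.8232088709110323e-03 -7.2054944552034698e-04
coif3	lo	-3.7935128643808019e-03 7.7825964256727463e-03 2.3452696142077168e-02 -6.5771911281469364e-02 -6.1123390002972552e-02 4.0517690240911824e-01 7.9377722262608719e-01 4.2848347637737000e-01 -7.1799821619154838e-02 -8.2301927106299827e-02 3.4555027573297738e-02 1.5880544863669452e-02 -9.0079761367306242e-03 -2.5745176881367972e-03 1.1175187708306303e-03 4.6621695982040288e-04 -7.0983302506379004e-05 -3.4599773197272781e-05
coif4	lo	8.9231390253700297e-04 -1.6294924252267860e-03 -7.3461679362680507e-03 1.6068947131575029e-02 2.6682304669604830e-02 -8.1266710249193727e-02 -5.6077319603569258e-02 4.1530842700068227e-01 7.8223893442428261e-01 4.3438603311435653e-01 -6.6627472366817167e-02 -9.6220424535952642e-02 3.9334422605589149e-02 2.5082253337949612e-02 -1.5211728187697211e-02 -5.6582838001308835e-03 3.7514346971460866e-03 1.2665610789256603e-03 -5.8902022463321654e-04 -2.5997433712225682e-04 6.2338854312787192e-05 3.1229861599195265e-05 -3.2596479400307510e-06 -1.7849909144933469e-06
coif5	lo	-2.1208186206749400e-04 3.5857774116175768e-04 2.1782943778456947e-03 -4.1593126275786402e-03 -1.0131584846900276e-02 2.3408322118927783e-02 2.8169744270532353e-02 -9.1921588060086087e-02 -5.2046670253554764e-02 4.2157126673075435e-01 7.7429362286032744e-01 4.3798230665916338e-01 -6.2037751574981960e-02 -1.0556315130733723e-01 4.1287530472117834e-02 3.2674799467057355e-02 -1.9758391600965465e-02 -9.1595073386761625e-03 6.7615202206204169e-03 2.4315754425382886e-03 -1.6616273039298788e-03 -6.3755892612588115e-04 3.0185794166824478e-04 1.4035632812373243e-04 -4.1219861924265501e-05 -2.1270221672515614e-05 3.7007277113394796e-06 2.0612203985788783e-06 -1.6237995172048338e-07 -9.6040101127678941e-08
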