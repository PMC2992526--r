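((((((((N21:0.05414667143,N12:0.05414667143):0.0184953321,(((P04:0.1,P05:0.1):0.2,P06:0.3):0.4,N14:0.04910026574):0.02354173778):0.1778900349,(N02:0.1607824493,((N20:0.02981725329,N11:0.02981725329):0.06075501258,(N37:0.04597303629,N25:0.04597303629):0.04459922958):0.0702101834):0.08974958918):0.2244628918,(N23:0.2523952023,N15:0.2523952023):0.2225997279):0.1733379362,((N08:0.07021510352,(N26:0.05811144981,N09:0.05811144981):0.01210365371):0.03572019081,N34:0.1059352943):0.5423975721):0.02515614242,((N17:0.2207513973,N13:0.2207513973):0.4007071314,(N27:0.04941431763,((P10:0.1,P11:0.1):0.2,P12:0.3):0.4):0.5720442111):0.05203048016):0.0524307899,((N01:0.2484194567,(N19:0.2153841864,N24:0.2153841864):0.03303527031):0.4378878063,(((((P07:0.1,P08:0.1):0.2,P09:0.3):0.4,N35:0.08300988968):0.004122825787,N06:0.08713271547):0.2446400753,N32:0.3317727907):0.3545344723):0.03961253576):0.2740802012,(((((N18:0.2252019177,N29:0.2252019177):0.1745314489,N22:0.3997333667):0.1612379394,N33:0.5609713061):0.03723166812,(N05:0.19073775,(((N30:0.08220991588,N36:0.08220991588):0.1024241555,(N28:0.0345722692,((P01:0.1,P02:0.1):0.2,P03:0.3):0.4):0.1500618022):0.004535512339,(N38:0.1640139388,N03:0.1640139388):0.02515564491):0.001568166309):0.4074652242):0.003011161877,((((N04:0.07159596667,N31:0.07159596667):0.01909121132,N10:0.09068717799):0.1011027645,N07:0.1917899425):0.1692330312,N16:0.3610229737):0.2401911624):0.3987858639);
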