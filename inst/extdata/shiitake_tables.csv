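"substrate","bagasse_pct","wheatbran_pct","beechsawdust_pct","days_to_highest","rl_mean_cm","rl_letters","rr_mean_cm_per_day","rr_letters"
"S_1",0,0,0,,0,"v",0,"z"
"S_2",0,0,25,40,6.8,"r",0.17,"wx"
"S_3",0,0,50,40,6.8,"r",0.17,"wx"
"S_4",0,0,100,40,6.8,"r",0.17,"wx"
"S_5",0,25,0,30,9.15,"h-n",0.305,"n-r"
"S_6",0,25,25,30,10.1,"bcd",0.337,"f-i"
"S_7",0,25,50,30,9.62,"e-i",0.321,"j-m"
"S_8",0,25,100,30,9.02,"lmn",0.301,"pqr"
"S_9",0,50,0,30,9.3,"h-n",0.31,"L-q"
"S_10",0,50,25,30,9.6,"e-j",0.32,"j-o"
"S_11",0,50,50,30,10.57,"a",0.3525,"de"
"S_12",0,50,100,30,9.57,"e-k",0.319,"k-o"
"S_13",0,100,0,30,10.3,"abc",0.343,"efg"
"S_14",0,100,25,30,9.75,"d-h",0.325,"h-l"
"S_15",0,100,50,30,9.9,"def",0.33,"h-k"
"S_16",0,100,100,30,10.6,"a",0.353,"de"
"S_17",25,0,0,35,5.2,"u",0.15,"y"
"S_18",25,0,25,35,5.2,"u",0.148,"y"
"S_19",25,0,50,35,9,"lmn",0.257,"t"
"S_20",25,0,100,30,9.07,"k-n",0.302,"pqr"
"S_21",25,25,0,30,9.47,"f-m",0.316,"k-p"
"S_22",25,25,25,30,9.47,"f-m",0.316,"k-p"
"S_23",25,25,50,30,9.72,"d-h",0.324,"i-m"
"S_24",25,25,100,30,10.02,"cde",0.334,"g-j"
"S_25",25,50,0,25,9.77,"d-h",0.391,"a"
"S_26",25,50,25,30,10.45,"ab",0.348,"ef"
"S_27",25,50,50,30,9.37,"g-m",0.312,"L-q"
"S_28",25,50,100,30,9.15,"i-n",0.305,"n-r"
"S_29",25,100,0,25,9.67,"e-i",0.387,"a"
"S_30",25,100,25,25,9.57,"f-l",0.383,"a"
"S_31",25,100,50,25,9.5,"f-l",0.38,"ab"
"S_32",25,100,100,25,9.2,"i-n",0.368,"c"
"S_33",50,0,0,35,5.05,"u",0.144,"y"
"S_34",50,0,25,35,5.12,"u",0.146,"y"
"S_35",50,0,50,30,5.12,"u",0.171,"w"
"S_36",50,0,100,30,7.2,"q",0.24,"u"
"S_37",50,25,0,30,9.6,"f-j",0.32,"j-o"
"S_38",50,25,25,30,9.6,"f-j",0.32,"j-o"
"S_39",50,25,50,30,9.72,"d-h",0.32,"j-o"
"S_40",50,25,100,30,10.12,"bcd",0.338,"fgh"
"S_41",50,50,0,30,9.12,"j-n",0.304,"o-r"
"S_42",50,50,25,25,9.67,"d-i",0.387,"a"
"S_43",50,50,50,25,9.3,"h-n",0.372,"bc"
"S_44",50,50,100,25,9.27,"i-n",0.371,"bc"
"S_45",50,100,0,25,9.82,"d-g",0.393,"a"
"S_46",50,100,25,25,9.75,"d-h",0.39,"a"
"S_47",50,100,50,30,10.57,"a",0.352,"de"
"S_48",50,100,100,30,8.97,"mn",0.299,"qr"
"S_49",100,0,0,40,5.97,"t",0.149,"y"
"S_50",100,0,25,40,6.05,"st",0.151,"y"
"S_51",100,0,50,40,6.32,"s",0.158,"xy"
"S_52",100,0,100,40,5.87,"t",0.147,"y"
"S_53",100,25,0,30,9.45,"f-m",0.315,"k-p"
"S_54",100,25,25,30,10.35,"abc",0.345,"efg"
"S_55",100,25,50,30,8.82,"no",0.294,"rs"
"S_56",100,25,100,30,8.57,"o",0.286,"s"
"S_57",100,50,0,35,7.62,"p",0.218,"v"
"S_58",100,50,25,30,9.27,"h-m",0.309,"L-q"
"S_59",100,50,50,30,9.25,"h-m",0.308,"m-r"
"S_60",100,50,100,30,9.25,"h-m",0.308,"m-r"
"S_61",100,100,0,30,9.35,"g-m",0.312,"L-q"
"S_62",100,100,25,25,9.1,"k-n",0.364,"cd"
"S_63",100,100,50,25,9.62,"e-i",0.385,"a"
"S_64",100,100,100,25,9.6,"e-j",0.384,"a"
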