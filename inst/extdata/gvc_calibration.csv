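"delta","k_max"
0,0
0.29013334754354,23
0.295761663695363,23
0.295940735590736,23
0.295963119778994,25
0.296225298737088,25
0.296718139185602,25
0.297544794152334,25
0.297627125622066,25
0.299170374718116,25
0.299276358961529,28
0.410784659295253,40
0.41552329565724,48
0.418461151385374,48
0.418866720544147,48
0.418888019651162,48
0.421235325863889,49
0.422591681837459,49
0.422678677606459,49
0.423217943378064,49
0.425057494643478,58
0.508711602660344,66
0.509338034833458,70
0.512021627947847,88
0.512397685412847,88
0.513714535958934,88
0.515181088366727,88
0.515743114160667,88
0.517847474211249,88
0.520374751999042,88
0.523083907926755,105
0.578787335932374,105
0.581025831553897,105
0.587977335057039,108
0.591881620967934,108
0.592013532844718,144
0.592561307419499,144
0.596209344621991,144
0.597824549364941,181
0.599039148441657,181
0.607603798365043,181
0.655770079525046,181
0.656903442179587,298
0.658504523504066,298
0.659481932411793,298
0.660539342825115,298
0.666356373238463,298
0.670481083518611,298
0.671685306432097,298
0.67277972261963,298
0.67837313279773,298
0.715249653009691,314
0.722767212195533,314
0.724013434577776,314
0.725099024452386,382
0.725721414344961,382
0.72846564689967,382
0.729084064016449,382
0.729552967475182,382
0.731465727571875,382
0.732208253647572,382
0.76482853304671,561
0.768392850322036,561
0.775417952801863,561
0.778020138686218,561
0.782216367818121,561
0.784230170716556,561
0.784364784718946,561
0.786676407305193,561
0.788942410792857,561
0.790174570336915,677
0.824703475220986,677
0.830390350263589,677
0.831083946490159,677
0.834638175269243,677
0.836378539160156,677
0.838242414487573,677
0.839396442216547,677
0.845915080257414,677
0.852080443135315,800
0.856321357725776,800
0.865881207582397,800
0.876324900335595,800
0.883001467133578,800
0.884345116029372,800
0.886401734160448,800
0.890542071855083,800
0.89688575939405,800
0.899288477462635,800
0.903212498775815,800
0.905314993699821,800
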