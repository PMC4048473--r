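"time","X1","X2","X3","X4"
0,1.4,2.7,1.2,0.4
0.5,0.574332873364115,3.10414952668212,2.15024085804784,0.220977143939831
1,0.321731078569179,2.43086189234736,2.64285849382729,0.135365415230292
1.5,0.302529529490954,1.96099107639758,2.6279915631569,0.120036942439106
2,0.339803263039365,1.82157021975247,2.416205237847,0.126199638933958
2.5,0.385652463705118,1.86737488109574,2.2431528752361,0.136868204506996
3,0.411543394839252,1.95905766819534,2.17693910769123,0.144162033245229
3.5,0.413918638088485,2.01781494705975,2.18409301572185,0.146010247215626
4,0.406338319375979,2.03138735974507,2.21211540582266,0.144759462290591
4.5,0.399866960941739,2.02148198145958,2.23118866739201,0.143172452411786
5,0.397482598027039,2.00923715124556,2.236221564879,0.142389592673511
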