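gene1,gene2,rho
Arntl,Npas2,0.927761441974642
Arntl,Clock,0.932098698548955
Arntl,Cry1,0.470990443462069
Arntl,Cry2,-0.931776239430213
Arntl,Nr1d1,-0.935164060124916
Arntl,Nr1d2,-0.938266248494394
Arntl,Per1,-0.934472309347247
Arntl,Per2,-0.935240077923159
Arntl,Per3,-0.927703305379526
Arntl,Dbp,-0.933498230335359
Arntl,Tef,-0.932257346903336
Npas2,Clock,0.929361528733395
Npas2,Cry1,0.469366541806867
Npas2,Cry2,-0.928365679920156
Npas2,Nr1d1,-0.926982307128515
Npas2,Nr1d2,-0.937766582528093
Npas2,Per1,-0.929289201968893
Npas2,Per2,-0.939346198395421
Npas2,Per3,-0.928461967543008
Npas2,Dbp,-0.936703699621067
Npas2,Tef,-0.934631218948571
Clock,Cry1,0.476431827196153
Clock,Cry2,-0.926096970464143
Clock,Nr1d1,-0.938757660481133
Clock,Nr1d2,-0.93190276589773
Clock,Per1,-0.93014340986949
Clock,Per2,-0.935752678357251
Clock,Per3,-0.930925165547091
Clock,Dbp,-0.94164999764076
Clock,Tef,-0.938403214634489
Cry1,Cry2,-0.450469759265081
Cry1,Nr1d1,-0.440794391274638
Cry1,Nr1d2,-0.472544811078747
Cry1,Per1,-0.45388914946167
Cry1,Per2,-0.465030996587348
Cry1,Per3,-0.470918469264253
Cry1,Dbp,-0.480583728645621
Cry1,Tef,-0.448289349310744
Cry2,Nr1d1,0.928558724031278
Cry2,Nr1d2,0.929783249095791
Cry2,Per1,0.923440446966876
Cry2,Per2,0.925469618443276
Cry2,Per3,0.921499999894595
Cry2,Dbp,0.924889174019101
Cry2,Tef,0.932686263766046
Nr1d1,Nr1d2,0.93746515131358
Nr1d1,Per1,0.938279858924905
Nr1d1,Per2,0.94023574658676
Nr1d1,Per3,0.93403617194145
Nr1d1,Dbp,0.934036595327979
Nr1d1,Tef,0.937957532620349
Nr1d2,Per1,0.940053568630177
Nr1d2,Per2,0.934493401765124
Nr1d2,Per3,0.93228522882016
Nr1d2,Dbp,0.936924828473565
Nr1d2,Tef,0.938302349182731
Per1,Per2,0.931921747225963
Per1,Per3,0.927865358925171
Per1,Dbp,0.921631272079835
Per1,Tef,0.938893800277211
Per2,Per3,0.929379635155591
Per2,Dbp,0.932174992946216
Per2,Tef,0.937654040198798
Per3,Dbp,0.930426020752419
Per3,Tef,0.930161220230285
Dbp,Tef,0.935768240566989
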