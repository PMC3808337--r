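"code","winter_mean","winter_sd","summer_mean","summer_sd"
"gppTOmpb",413.089999999998,0,183.599999999999,0
"mpbTOres",65.8052278957539,28.3239751040228,21.188141630178,9.86381205310121
"mpbTObdc",110.75,9.6481858166387e-15,51,6.26203676682528e-15
"mpbTOmfb",1.78365867221356,1.08307841721398,2.036258989838,1.27743651825615
"mpbTOnem",44.0998564693698,28.326076313523,14.7146375452526,12.3465846833846
"mpbTOdep",94.1669794677608,30.9113061196677,33.9239029625149,17.3162888844521
"mpbTOomn",17.1399299955729,9.64164693551087,21.9432462069106,13.0446740832919
"mpbTOsuf",23.1814683039701,10.8179565465852,26.5911284602595,14.1004622591557
"mpbTOexp",56.1628791953591,36.022774174066,12.2026842050462,10.960867689376
"bcbTOres",186.597070909885,51.3669854883807,121.221718730816,43.5037630306385
"bcbTObdc",138.156081040213,13.629207688428,31.4905279042365,18.1148457082672
"bcbTOmfb",0.0859999999999628,5.84775644182593e-15,0.0350000000000274,4.40985316156002e-15
"bcbTOnem",0.10699999999994,6.79277743829172e-15,0.110000000000078,9.95514207896568e-15
"bcbTOdep",6.11000000000014,1.06788051669215e-14,11.25,4.72256221767923e-15
"bcbTOomn",11.3282052468071,9.56910804004261,21.4090094430063,16.2155831836779
"bcbTOsuf",11.6527137129799,9.49548165495348,26.0654626527572,16.3509136929807
"bcbTOvrb",1.87999999999986,4.72916689770632e-15,3.58000000000002,1.60277877439028e-14
"mfbTOres",1.31615183208007,0.138899972955135,1.56197787272122,0.172869666560719
"mfbTOcar",0.380139535882375,0.275845887815289,0.610176871749209,0.386847549209084
"mfbTOomn",0.372803026833697,0.273122766695526,0.60661644112844,0.385651652868576
"mfbTOcbr",0.305625393487656,0.243819072147587,NA,NA
"mfbTObpc",1.27816430956314,0.357252846819557,1.49094168755013,0.423592694919054
"nemTOres",4.37790502688105,0.558816421845248,5.33234358153308,0.682065695443016
"nemTOcar",9.50106352912799,5.83153750130043,10.0609847639337,6.7629233515766
"nemTOomn",6.11176387462244,4.80210292410899,9.00855875301413,6.53620121292992
"nemTObpc",71.6100143234515,14.1929787472638,83.764997092625,18.8869105827339
"impTOcar",22.3450533565177,8.51732178561745,58.4961745877554,20.201281773666
"carTOres",11.7419344821552,2.25531126675276,24.7211006065444,6.17589962522244
"carTObpc",28.1663424591053,10.5340667129038,52.4054794447197,20.0497304965737
"carTOcbr",1.01815592594737,0.844772998246253,NA,NA
"carTOexp",18.9101281330705,5.48325955053514,39.0515445648749,11.6207928643053
"impTOdep",47.9123998878401,19.3281855493419,168.9816165962,36.1439771787039
"depTOres",29.6236383528722,4.08504982834553,50.0934255152623,13.6816923526019
"depTOcar",20.2800606202541,12.4885092301284,29.4244467139447,21.1699424376737
"depTOomn",9.24635472144506,8.12809910050728,21.0490835771878,16.6111731610838
"depTOcbr",4.31707376906166,1.09165486640239,NA,NA
"depTObpc",81.2052185236072,27.9975311334403,85.9401183345232,26.9619120568029
"depTOexp",21.0618955826542,13.6686310722408,29.7695341955541,23.0519849365984
"impTOomn",14.6263679038411,6.32959096984612,43.6647403934638,17.109637408043
"omnTOres",10.7008348187444,1.14532868570997,25.1471488605235,3.64919995593677
"omnTOcbr",1.01024806680012,0.835905698219074,NA,NA
"omnTObpc",36.9849743900856,9.98565343104099,72.297292218123,22.541305730579
"omnTOexp",19.8775155344614,4.06127784025614,45.0883875329206,10.4409626967162
"impTOsus",16.8057544324194,2.67505324433145,42.2758514910552,6.48497633942287
"susTOres",4.08424018781905,1.07529955832494,10.1784818832188,2.67266482589804
"susTOcar",1.95890720869001,1.51526867627058,5.5068460350875,4.13675948438902
"susTOomn",1.74877614431684,1.4122600629254,5.20232972867529,4.00329606963114
"susTOcbr",0.746675196345463,0.657136900400691,NA,NA
"susTObpc",6.28942554414097,1.86293908295365,16.1146120720078,4.74509500403055
"susTOexp",1.97773015110716,1.52369734923333,5.27358177206579,4.05536267724823
"impTOsuf",11.987035686932,5.00270196112517,34.8600442572478,12.2553665975365
"sufTOres",7.94984632968667,0.922742126187041,18.2171805369993,2.86027934012401
"sufTOcar",5.37133674980622,3.88697659847751,12.0794956436686,8.65138038141067
"sufTOomn",3.97606728681862,3.24173937288792,10.6408094263747,8.0221700975801
"sufTOcbr",0.913564164458388,0.777927039713382,NA,NA
"sufTObpc",25.5002366565915,8.21129952127798,44.2572360641353,16.1726597911931
"sufTOexp",5.40629864024406,3.85821570105533,10.6341187711764,8.10825879214144
"cbrTOres",1.65450231518759,0.582440399445654,NA,NA
"cbrTObpc",1.24457340732444,0.435852909969399,NA,NA
"cbrTOexp",5.41226679358824,1.55183541397294,NA,NA
"vrbTObdc",0.941605605296267,0.542687006870823,1.80001491763056,1.03395688264378
"vrbTOext",0.938394394703467,0.542687006870823,1.77998508236939,1.03395688264378
"bpcTOmfb",1.78322542563349,1.08204732196551,2.19845388331111,1.29010447323215
"bpcTOnem",47.3938902847131,27.9446839933979,93.3422466458533,25.2329475046584
"bpcTOdep",17.5448622142934,12.6040601430806,2.12108877775751,1.74798479874302
"bpcTOomn",4.02330460983403,2.36486045885087,9.00843464180608,6.68695210938806
"bpcTOsuf",2.29613212372354,1.67074797150433,8.31220507208994,4.6477472780449
"bpcTObdc",106.069384264376,52.5716144869487,181.368949162128,43.2662324990144
"bpcTOexp",73.1681506912963,46.0442067170222,59.9192987307383,39.9256703392947
"bdcTObcb",355.917070909885,51.3669854883807,215.161718730816,43.5037630306385
"bdcTOexp",NA,NA,50.4977732531789,40.472234761853
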