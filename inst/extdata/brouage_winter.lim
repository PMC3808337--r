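# Brouage mudflat benthic food-web LIM, winter model
# Units: mgC m-2 per low tide.
# Published rate and diet constraints are encoded verbatim;
# absolute respiration/consumption/egestion/import bounds depend on
# biomasses and densities that were never published and are
# RECONSTRUCTED (see brouage_params()): regenerate with
# write_lim(brouage_model("winter"), ...)
SEASON winter
COMPARTMENTS
mpb  Microphytobenthos  living
bcb  Benthic bacteria  living
mfb  Foraminifera and copepods  living
nem  Nematodes  living
dep  Deposit feeders  living
sus  Suspension feeders  living
suf  Facultative suspension feeders  living
omn  Omnivorous species  living
car  Carnivorous species  living
cbr  Carnivorous birds  living
vrb  Benthic viruses  living
bpc  Benthic particulate carbon  pool
bdc  Benthic dissolved carbon  pool
FLOWS
gppTOmpb
mpbTOres
mpbTObdc
mpbTOmfb
mpbTOnem
mpbTOdep
mpbTOomn
mpbTOsuf
mpbTOexp
bcbTOres
bcbTObdc
bcbTOmfb
bcbTOnem
bcbTOdep
bcbTOomn
bcbTOsuf
bcbTOvrb
mfbTOres
mfbTOcar
mfbTOomn
mfbTOcbr
mfbTObpc
nemTOres
nemTOcar
nemTOomn
nemTObpc
impTOcar
carTOres
carTObpc
carTOcbr
carTOexp
impTOdep
depTOres
depTOcar
depTOomn
depTOcbr
depTObpc
depTOexp
impTOomn
omnTOres
omnTOcbr
omnTObpc
omnTOexp
impTOsus
susTOres
susTOcar
susTOomn
susTOcbr
susTObpc
susTOexp
impTOsuf
sufTOres
sufTOcar
sufTOomn
sufTOcbr
sufTObpc
sufTOexp
cbrTOres
cbrTObpc
cbrTOexp
vrbTObdc
vrbTOext
bpcTOmfb
bpcTOnem
bpcTOdep
bpcTOomn
bpcTOsuf
bpcTObdc
bpcTOexp
bdcTObcb
MEASURED
gppTOmpb = 413.09
mpbTObdc = 110.75
bdcTObcb - bcbTOres = 169.32
bcbTOmfb = 0.086
bcbTOnem = 0.107
bcbTOdep = 6.11
bcbTOvrb = 1.88
CONSTRAINTS
0.05*gppTOmpb - mpbTOres <= 0
-0.3*gppTOmpb + mpbTOres <= 0
0.5*mpbTOmfb + 0.5*bcbTOmfb + 0.5*bpcTOmfb - 0.5*mfbTObpc - mfbTOres <= 0
-0.7*mpbTOmfb - 0.7*bcbTOmfb - 0.7*bpcTOmfb + 0.7*mfbTObpc + mfbTOres <= 0
0.1*mpbTOnem + 0.1*bcbTOnem + 0.1*bpcTOnem - 0.1*nemTObpc - nemTOres <= 0
-0.4*mpbTOnem - 0.4*bcbTOnem - 0.4*bpcTOnem + 0.4*nemTObpc + nemTOres <= 0
0.3*mfbTOcar + 0.3*nemTOcar + 0.3*depTOcar + 0.3*susTOcar + 0.3*sufTOcar + 0.3*impTOcar - 0.3*carTObpc - carTOres <= 0
-0.5*mfbTOcar - 0.5*nemTOcar - 0.5*depTOcar - 0.5*susTOcar - 0.5*sufTOcar - 0.5*impTOcar + 0.5*carTObpc + carTOres <= 0
0.3*mpbTOdep + 0.3*bcbTOdep + 0.3*bpcTOdep + 0.3*impTOdep - 0.3*depTObpc - depTOres <= 0
-0.5*mpbTOdep - 0.5*bcbTOdep - 0.5*bpcTOdep - 0.5*impTOdep + 0.5*depTObpc + depTOres <= 0
0.3*mpbTOomn + 0.3*bcbTOomn + 0.3*mfbTOomn + 0.3*nemTOomn + 0.3*depTOomn + 0.3*susTOomn + 0.3*sufTOomn + 0.3*bpcTOomn + 0.3*impTOomn - 0.3*omnTObpc - omnTOres <= 0
-0.5*mpbTOomn - 0.5*bcbTOomn - 0.5*mfbTOomn - 0.5*nemTOomn - 0.5*depTOomn - 0.5*susTOomn - 0.5*sufTOomn - 0.5*bpcTOomn - 0.5*impTOomn + 0.5*omnTObpc + omnTOres <= 0
0.3*impTOsus - 0.3*susTObpc - susTOres <= 0
-0.5*impTOsus + 0.5*susTObpc + susTOres <= 0
0.3*mpbTOsuf + 0.3*bcbTOsuf + 0.3*bpcTOsuf + 0.3*impTOsuf - 0.3*sufTObpc - sufTOres <= 0
-0.5*mpbTOsuf - 0.5*bcbTOsuf - 0.5*bpcTOsuf - 0.5*impTOsuf + 0.5*sufTObpc + sufTOres <= 0
0.39*bdcTObcb - bcbTOres <= 0
-0.89*bdcTObcb + bcbTOres <= 0
0.23*mpbTOmfb + 0.23*bcbTOmfb + 0.23*bpcTOmfb - mfbTObpc <= 0
-0.43*mpbTOmfb - 0.43*bcbTOmfb - 0.43*bpcTOmfb + mfbTObpc <= 0
0.7*mpbTOnem + 0.7*bcbTOnem + 0.7*bpcTOnem - nemTObpc <= 0
-0.94*mpbTOnem - 0.94*bcbTOnem - 0.94*bpcTOnem + nemTObpc <= 0
0.25*mfbTOcar + 0.25*nemTOcar + 0.25*depTOcar + 0.25*susTOcar + 0.25*sufTOcar + 0.25*impTOcar - carTObpc <= 0
-0.6*mfbTOcar - 0.6*nemTOcar - 0.6*depTOcar - 0.6*susTOcar - 0.6*sufTOcar - 0.6*impTOcar + carTObpc <= 0
0.25*mpbTOdep + 0.25*bcbTOdep + 0.25*bpcTOdep + 0.25*impTOdep - depTObpc <= 0
-0.6*mpbTOdep - 0.6*bcbTOdep - 0.6*bpcTOdep - 0.6*impTOdep + depTObpc <= 0
0.25*mpbTOomn + 0.25*bcbTOomn + 0.25*mfbTOomn + 0.25*nemTOomn + 0.25*depTOomn + 0.25*susTOomn + 0.25*sufTOomn + 0.25*bpcTOomn + 0.25*impTOomn - omnTObpc <= 0
-0.6*mpbTOomn - 0.6*bcbTOomn - 0.6*mfbTOomn - 0.6*nemTOomn - 0.6*depTOomn - 0.6*susTOomn - 0.6*sufTOomn - 0.6*bpcTOomn - 0.6*impTOomn + omnTObpc <= 0
0.25*impTOsus - susTObpc <= 0
-0.6*impTOsus + susTObpc <= 0
0.25*mpbTOsuf + 0.25*bcbTOsuf + 0.25*bpcTOsuf + 0.25*impTOsuf - sufTObpc <= 0
-0.6*mpbTOsuf - 0.6*bcbTOsuf - 0.6*bpcTOsuf - 0.6*impTOsuf + sufTObpc <= 0
-0.5*mpbTOdep + 0.5*bpcTOdep <= 0
0*mpbTOdep - bpcTOdep <= 0
-0.35*mpbTOomn + 0.65*bpcTOomn <= 0
0.14*mpbTOomn - 0.86*bpcTOomn <= 0
-0.24*mpbTOsuf + 0.76*bpcTOsuf <= 0
0.01*mpbTOsuf - 0.99*bpcTOsuf <= 0
0*mpbTOdep - bpcTOdep <= 0
-0.31*mpbTOdep + 0.69*bpcTOdep <= 0
0*mpbTOomn - bpcTOomn <= 0
-0.24*mpbTOomn + 0.76*bpcTOomn <= 0
0*mpbTOsuf - bpcTOsuf <= 0
-0.17*mpbTOsuf + 0.83*bpcTOsuf <= 0
-mfbTOres <= -0.9600000000000002
mfbTOres <= 1.5
-nemTOres <= -3.4560000000000004
nemTOres <= 5.4
-mpbTOmfb - bcbTOmfb - bpcTOmfb <= -0.5
mpbTOmfb + bcbTOmfb + bpcTOmfb <= 2e+01
-mpbTOnem - bcbTOnem - bpcTOnem <= -4.5
mpbTOnem + bcbTOnem + bpcTOnem <= 112.5
-mfbTOcar - nemTOcar - depTOcar - susTOcar - sufTOcar - impTOcar <= -8.620689655172415
mfbTOcar + nemTOcar + depTOcar + susTOcar + sufTOcar + impTOcar <= 7.5e+02
-carTOres <= -2.25
carTOres <= 15
-impTOcar <= -7.5
impTOcar <= 37.5
-mpbTOdep - bcbTOdep - bpcTOdep - impTOdep <= -20.114942528735632
mpbTOdep + bcbTOdep + bpcTOdep + impTOdep <= 1.75e+03
-depTOres <= -5.25
depTOres <= 35
-impTOdep <= -17.5
impTOdep <= 87.5
-mpbTOomn - bcbTOomn - mfbTOomn - nemTOomn - depTOomn - susTOomn - sufTOomn - bpcTOomn - impTOomn <= -6.8965517241379315
mpbTOomn + bcbTOomn + mfbTOomn + nemTOomn + depTOomn + susTOomn + sufTOomn + bpcTOomn + impTOomn <= 6e+02
-omnTOres <= -1.8
omnTOres <= 12
-impTOomn <= -6
impTOomn <= 3e+01
-impTOsus <= -4.597701149425287
impTOsus <= 4e+02
-susTOres <= -1.2
susTOres <= 8
-impTOsus <= -4
impTOsus <= 2e+01
-mpbTOsuf - bcbTOsuf - bpcTOsuf - impTOsuf <= -5.172413793103448
mpbTOsuf + bcbTOsuf + bpcTOsuf + impTOsuf <= 4.5e+02
-sufTOres <= -1.35
sufTOres <= 9
-impTOsuf <= -4.5
impTOsuf <= 22.5
-mfbTOcbr - carTOcbr - depTOcbr - omnTOcbr - susTOcbr - sufTOcbr <= -2.4390243902439024
mfbTOcbr + carTOcbr + depTOcbr + omnTOcbr + susTOcbr + sufTOcbr <= 1e+01
-cbrTOres <= -0.6504065040650406
cbrTOres <= 2.6666666666666665
-cbrTObpc <= -0.48780487804878037
cbrTObpc <= 1.9999999999999996
0.4*mfbTOcbr + 0.4*carTOcbr + 0.4*omnTOcbr + 0.4*susTOcbr + 0.4*sufTOcbr - 0.6*depTOcbr <= 0
END
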