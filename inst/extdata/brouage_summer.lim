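# Brouage mudflat benthic food-web LIM, summer model
# Units: mgC m-2 per low tide.
# Published rate and diet constraints are encoded verbatim;
# absolute respiration/consumption/egestion/import bounds depend on
# biomasses and densities that were never published and are
# RECONSTRUCTED (see brouage_params()): regenerate with
# write_lim(brouage_model("summer"), ...)
SEASON summer
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
mfbTObpc
nemTOres
nemTOcar
nemTOomn
nemTObpc
impTOcar
carTOres
carTObpc
carTOexp
impTOdep
depTOres
depTOcar
depTOomn
depTObpc
depTOexp
impTOomn
omnTOres
omnTObpc
omnTOexp
impTOsus
susTOres
susTOcar
susTOomn
susTObpc
susTOexp
impTOsuf
sufTOres
sufTOcar
sufTOomn
sufTObpc
sufTOexp
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
bdcTOexp
MEASURED
gppTOmpb = 183.6
mpbTObdc = 51
bdcTObcb - bcbTOres = 93.94
bcbTOmfb = 0.035
bcbTOnem = 0.11
bcbTOdep = 11.25
bcbTOvrb = 3.58
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
0*mpbTOdep - bpcTOdep <= 0
-0.74*mpbTOomn + 0.26*bpcTOomn <= 0
0.09*mpbTOomn - 0.91*bpcTOomn <= 0
-0.35*mpbTOsuf + 0.65*bpcTOsuf <= 0
0.18*mpbTOsuf - 0.82*bpcTOsuf <= 0
-0.11*mpbTOdep + 0.89*bpcTOdep <= 0
0*mpbTOomn - bpcTOomn <= 0
-0.44*mpbTOomn + 0.56*bpcTOomn <= 0
0*mpbTOsuf - bpcTOsuf <= 0
-0.29*mpbTOsuf + 0.71*bpcTOsuf <= 0
-mfbTOres <= -1.1520000000000001
mfbTOres <= 1.8
-nemTOres <= -4.224
nemTOres <= 6.6000000000000005
-mpbTOmfb - bcbTOmfb - bpcTOmfb <= -0.6
mpbTOmfb + bcbTOmfb + bpcTOmfb <= 24
-mpbTOnem - bcbTOnem - bpcTOnem <= -5.5
mpbTOnem + bcbTOnem + bpcTOnem <= 137.5
-mfbTOcar - nemTOcar - depTOcar - susTOcar - sufTOcar - impTOcar <= -10.344827586206897
mfbTOcar + nemTOcar + depTOcar + susTOcar + sufTOcar + impTOcar <= 9e+02
-carTOres <= -5.4
carTOres <= 36
-impTOcar <= -18
impTOcar <= 9e+01
-mpbTOdep - bcbTOdep - bpcTOdep - impTOdep <= -24.137931034482758
mpbTOdep + bcbTOdep + bpcTOdep + impTOdep <= 2.1e+03
-depTOres <= -12.6
depTOres <= 84
-impTOdep <= -42
impTOdep <= 2.1e+02
-mpbTOomn - bcbTOomn - mfbTOomn - nemTOomn - depTOomn - susTOomn - sufTOomn - bpcTOomn - impTOomn <= -8.620689655172415
mpbTOomn + bcbTOomn + mfbTOomn + nemTOomn + depTOomn + susTOomn + sufTOomn + bpcTOomn + impTOomn <= 7.5e+02
-omnTOres <= -4.5
omnTOres <= 3e+01
-impTOomn <= -15
impTOomn <= 75
-impTOsus <= -5.747126436781609
impTOsus <= 5e+02
-susTOres <= -3
susTOres <= 2e+01
-impTOsus <= -1e+01
impTOsus <= 5e+01
-mpbTOsuf - bcbTOsuf - bpcTOsuf - impTOsuf <= -6.32183908045977
mpbTOsuf + bcbTOsuf + bpcTOsuf + impTOsuf <= 5.5e+02
-sufTOres <= -3.3000000000000003
sufTOres <= 22
-impTOsuf <= -11
impTOsuf <= 55
END
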