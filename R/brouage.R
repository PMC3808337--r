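# Seasonal food-web models of the Brouage mudflat (Marennes-Oleron Bay).
#
# Two linear inverse models of the benthic food web at low tide: February
# (shorebirds present, 13 compartments / 70 flows) and July (shorebirds
# absent, 12 compartments / 62 flows).  Flow unit: mgC m-2 per low tide
# (LT).  Published rate constraints (respiration fractions, net growth
# efficiencies, egestion fractions, diet contributions) are encoded
# verbatim; absolute process bounds depend on biomasses and densities
# that were never published and are reconstructed here as documented
# `brouage_params()` entries.

#' Carbon content of a bacterial cell from its biovolume
#'
#' Allometric conversion `133.754 * V^0.438` (fgC per cell, V in um^3).
#'
#' @param V cell biovolume in cubic micrometres (>= 0).
#' @return femtograms of carbon per cell.
#' @examples
#' cell_carbon(0.28)
#' @export
cell_carbon <- function(V) {
  if (any(V < 0)) stop("biovolume must be >= 0")
  133.754 * V^0.438
}

#' Daily shorebird consumption bound
#'
#' Energy-balance sizing of shorebird consumption, `C = n * 3 * BMR / AE`:
#' birds at winter rest consume three times their basal metabolic rate,
#' corrected for assimilation efficiency.  Evaluated at the minimum and
#' maximum plausible bird densities this gives the lower and upper
#' consumption constraints.
#'
#' @param n bird density (individuals per m2, >= 0).
#' @param BMR basal metabolic rate (mgC per individual per day).
#' @param AE assimilation efficiency in (0, 1].
#' @return consumption in mgC m-2 d-1.
#' @export
bird_consumption_bound <- function(n, BMR, AE) {
  if (any(n < 0)) stop("bird density must be >= 0")
  if (any(AE <= 0 | AE > 1)) stop("assimilation efficiency must be in (0, 1]")
  n * 3 * BMR / AE
}

#' Constraint parameters of the Brouage models
#'
#' Published rates are fixed; absolute bounds derive from the biomass and
#' density entries below.  Entries marked "reconstructed" were never
#' published and are field-plausible values frozen once; they are chosen
#' so the constraint polytope is non-empty, and the bundled model files
#' flag them.
#'
#' @param season `"winter"` or `"summer"`.
#' @return list of class `brouage_params`.
#' @export
brouage_params <- function(season = c("winter", "summer")) {
  season <- match.arg(season)
  winter <- season == "winter"
  p <- list(
    season = season,
    ## ---- published rates ------------------------------------------------
    mpb_resp_frac  = c(0.05, 0.30),   # respiration as fraction of gpp
    nge_mfb        = c(0.5, 0.7),     # net growth efficiency bands
    nge_nem        = c(0.1, 0.4),
    nge_mac        = c(0.3, 0.5),
    bcb_resp_frac  = c(0.39, 0.89),   # respiration as fraction of DOC uptake
    egest_mfb      = c(0.23, 0.43),   # egestion as fraction of consumption
    egest_nem      = c(0.70, 0.94),
    egest_mac      = c(0.25, 0.60),
    pb_range       = c(0.01, 0.05),   # macrofauna production/biomass, d-1
    pc_max         = 0.87,            # production/consumption ceiling
    bird_ae        = 0.80,            # shorebird assimilation efficiency
    bird_density   = c(5e-5, 2.05e-4),# ind m-2; max published, min reconstructed
    # meiofauna biomass-specific respiration: 1.6-2.5 ul O2 h-1 mgC-1,
    # converted with 1 mL O2 = 0.4 mgC -> mgC h-1 per mgC biomass
    meio_resp_rate = c(1.6e-3 * 0.4, 2.5e-3 * 0.4),
    ## ---- reconstructed quantities --------------------------------------
    pc_min         = 0.10,            # production/consumption floor
    emersion_h     = 6,               # exposure hours per low tide
    lt_per_day     = 2,               # low tides per day
    # specific ingestion of nematodes, fraction of biomass per low tide
    nem_ingest_rate = c(0.005, 0.125),
    # specific consumption band for meiofauna (foraminifera + copepods)
    mfb_ingest_rate = c(0.002, 0.08),
    # macrofauna mass-specific respiration, d-1 (temperature dependent)
    mac_resp_rate  = if (winter) c(0.003, 0.02) else c(0.006, 0.04),
    # fraction of daily macrofauna production available as import
    import_frac    = if (winter) 0.5 else 1.0,
    # standing stocks, mgC m-2; dep summer anchored by the published
    # import bounds 42-210 mgC m-2 LT-1 (= B * P/B range)
    biomass = c(mfb = if (winter) 250 else 300,
                nem = if (winter) 900 else 1100,
                car = if (winter) 1500 else 1800,
                dep = if (winter) 3500 else 4200,
                omn = if (winter) 1200 else 1500,
                sus = if (winter) 800 else 1000,
                suf = if (winter) 900 else 1100),
    # minimum share of deposit feeders in the shorebird diet
    bird_dep_diet_min = 0.40
  )
  # BMR sized so consumption at the maximum density equals the published
  # 20 mgC m-2 d-1: BMR = 20 * AE / (3 * n_max)
  p$bird_bmr <- 20 * p$bird_ae / (3 * max(p$bird_density))
  class(p) <- c("brouage_params", "list")
  p
}

# measured field flows (equality rows), mgC m-2 LT-1
brouage_measured_values <- function(season) {
  w <- season == "winter"
  list(
    list(coef = c(gppTOmpb = 1), value = if (w) 413.09 else 183.6,
         label = "gppTOmpb"),
    list(coef = c(mpbTObdc = 1), value = if (w) 110.75 else 51,
         label = "mpbTObdc"),
    list(coef = c(bdcTObcb = 1, bcbTOres = -1),
         value = if (w) 169.32 else 93.94, label = "bcb_production"),
    list(coef = c(bcbTOmfb = 1), value = if (w) 0.086 else 0.035,
         label = "bcbTOmfb"),
    list(coef = c(bcbTOnem = 1), value = if (w) 0.107 else 0.11,
         label = "bcbTOnem"),
    list(coef = c(bcbTOdep = 1), value = if (w) 6.11 else 11.25,
         label = "bcbTOdep"),
    list(coef = c(bcbTOvrb = 1), value = if (w) 1.88 else 3.58,
         label = "bcbTOvrb"))
}

# published diet-contribution rows (Gx <= 0 form), per season:
# each row is a linear form over {mpbTOxxx, bpcTOxxx}
brouage_diet_rows <- function(season) {
  if (season == "summer") list(
    list(c(mpb = 0,     bpc = -1),    "dep", "diet_mpb_dep_up"),
    list(c(mpb = -0.74, bpc = 0.26),  "omn", "diet_mpb_omn_lo"),
    list(c(mpb = 0.09,  bpc = -0.91), "omn", "diet_mpb_omn_up"),
    list(c(mpb = -0.35, bpc = 0.65),  "suf", "diet_mpb_suf_lo"),
    list(c(mpb = 0.18,  bpc = -0.82), "suf", "diet_mpb_suf_up"),
    list(c(mpb = -0.11, bpc = 0.89),  "dep", "diet_bpc_dep_up"),
    list(c(mpb = 0,     bpc = -1),    "omn", "diet_bpc_omn_lo"),
    list(c(mpb = -0.44, bpc = 0.56),  "omn", "diet_bpc_omn_up"),
    list(c(mpb = 0,     bpc = -1),    "suf", "diet_bpc_suf_lo"),
    list(c(mpb = -0.29, bpc = 0.71),  "suf", "diet_bpc_suf_up"))
  else list(
    list(c(mpb = -0.5,  bpc = 0.5),   "dep", "diet_mpb_dep_lo"),
    list(c(mpb = 0,     bpc = -1),    "dep", "diet_mpb_dep_up"),
    list(c(mpb = -0.35, bpc = 0.65),  "omn", "diet_mpb_omn_lo"),
    list(c(mpb = 0.14,  bpc = -0.86), "omn", "diet_mpb_omn_up"),
    list(c(mpb = -0.24, bpc = 0.76),  "suf", "diet_mpb_suf_lo"),
    list(c(mpb = 0.01,  bpc = -0.99), "suf", "diet_mpb_suf_up"),
    list(c(mpb = 0,     bpc = -1),    "dep", "diet_bpc_dep_lo"),
    list(c(mpb = -0.31, bpc = 0.69),  "dep", "diet_bpc_dep_up"),
    list(c(mpb = 0,     bpc = -1),    "omn", "diet_bpc_omn_lo"),
    list(c(mpb = -0.24, bpc = 0.76),  "omn", "diet_bpc_omn_up"),
    list(c(mpb = 0,     bpc = -1),    "suf", "diet_bpc_suf_lo"),
    list(c(mpb = -0.17, bpc = 0.83),  "suf", "diet_bpc_suf_up"))
}

#' Build the Brouage winter or summer food-web model
#'
#' @param season `"winter"` (shorebirds present) or `"summer"`.
#' @param params a [brouage_params()] list.
#' @return a [lim_problem()]: 13 compartments / 70 flows in winter,
#'   12 / 62 in summer.
#' @export
brouage_model <- function(season = c("winter", "summer"),
                          params = brouage_params(season)) {
  season <- match.arg(season)
  winter <- season == "winter"

  ab <- c("mpb", "bcb", "mfb", "nem", "dep", "sus", "suf", "omn", "car",
          if (winter) "cbr", "vrb", "bpc", "bdc")
  nm <- c(mpb = "Microphytobenthos", bcb = "Benthic bacteria",
          mfb = "Foraminifera and copepods", nem = "Nematodes",
          dep = "Deposit feeders", sus = "Suspension feeders",
          suf = "Facultative suspension feeders",
          omn = "Omnivorous species", car = "Carnivorous species",
          cbr = "Carnivorous birds", vrb = "Benthic viruses",
          bpc = "Benthic particulate carbon",
          bdc = "Benthic dissolved carbon")
  comp <- compartment_table(ab, unname(nm[ab]),
                            living = !ab %in% c("bpc", "bdc"),
                            nonliving_pool = ab %in% c("bpc", "bdc"))

  mac <- c("car", "dep", "omn", "sus", "suf")
  flows <- c(
    "gppTOmpb",
    paste0("mpbTO", c("res", "bdc", "mfb", "nem", "dep", "omn", "suf", "exp")),
    paste0("bcbTO", c("res", "bdc", "mfb", "nem", "dep", "omn", "suf", "vrb")),
    paste0("mfbTO", c("res", "car", "omn", if (winter) "cbr", "bpc")),
    paste0("nemTO", c("res", "car", "omn", "bpc")),
    "impTOcar",
    paste0("carTO", c("res", "bpc", if (winter) "cbr", "exp")),
    "impTOdep",
    paste0("depTO", c("res", "car", "omn", if (winter) "cbr", "bpc", "exp")),
    "impTOomn",
    paste0("omnTO", c("res", if (winter) "cbr", "bpc", "exp")),
    "impTOsus",
    paste0("susTO", c("res", "car", "omn", if (winter) "cbr", "bpc", "exp")),
    "impTOsuf",
    paste0("sufTO", c("res", "car", "omn", if (winter) "cbr", "bpc", "exp")),
    if (winter) paste0("cbrTO", c("res", "bpc", "exp")),
    paste0("vrbTO", c("bdc", "ext")),
    paste0("bpcTO", c("mfb", "nem", "dep", "omn", "suf", "bdc", "exp")),
    "bdcTObcb",
    if (!winter) "bdcTOexp")

  food_in <- function(g) {
    ends <- flow_ends(flows)
    flows[ends$sink == g & !ends$source %in% BOUNDARY_SOURCES]
  }
  cset <- function(codes, k) setNames(rep(k, length(codes)), codes)

  le <- function(coef, rhs, label) list(coef = coef, dir = "<=",
                                        rhs = rhs, label = label)
  con <- list()
  add <- function(x) con[[length(con) + 1L]] <<- x

  ## respiration of microphytobenthos: between 5% and 30% of gpp
  add(le(c(gppTOmpb = params$mpb_resp_frac[1], mpbTOres = -1), 0,
         "mpb_resp_lo"))
  add(le(c(gppTOmpb = -params$mpb_resp_frac[2], mpbTOres = 1), 0,
         "mpb_resp_up"))

  ## net growth efficiency bands (meiofauna, nematodes, macrofauna)
  nge_band <- function(g, C, E, I, band) {
    lo <- band[1]; up <- band[2]
    resp <- paste0(g, "TOres")
    add(le(c(cset(C, lo), cset(I, lo), cset(E, -lo), cset(resp, -1)), 0,
           paste0("nge_", g, "_lo")))
    add(le(c(cset(C, -up), cset(I, -up), cset(E, up), cset(resp, 1)), 0,
           paste0("nge_", g, "_up")))
  }
  nge_band("mfb", food_in("mfb"), "mfbTObpc", character(0), params$nge_mfb)
  nge_band("nem", food_in("nem"), "nemTObpc", character(0), params$nge_nem)
  for (g in mac)
    nge_band(g, food_in(g), paste0(g, "TObpc"), paste0("impTO", g),
             params$nge_mac)

  ## bacterial respiration: 0.39-0.89 of DOC uptake
  add(le(c(bdcTObcb = params$bcb_resp_frac[1], bcbTOres = -1), 0,
         "bcb_resp_lo"))
  add(le(c(bdcTObcb = -params$bcb_resp_frac[2], bcbTOres = 1), 0,
         "bcb_resp_up"))

  ## egestion bands; macrofauna ingestion includes the import term
  egest_band <- function(g, C, E, band) {
    add(le(c(cset(C, band[1]), cset(E, -1)), 0, paste0("egest_", g, "_lo")))
    add(le(c(cset(C, -band[2]), cset(E, 1)), 0, paste0("egest_", g, "_up")))
  }
  egest_band("mfb", food_in("mfb"), "mfbTObpc", params$egest_mfb)
  egest_band("nem", food_in("nem"), "nemTObpc", params$egest_nem)
  for (g in mac)
    egest_band(g, c(food_in(g), paste0("impTO", g)), paste0(g, "TObpc"),
               params$egest_mac)

  ## diet contributions of mpb and bpc (isotope mixing bounds, published)
  for (row in brouage_diet_rows(season)) {
    k <- row[[1]]; g <- row[[2]]
    add(le(setNames(c(k[["mpb"]], k[["bpc"]]),
                    paste0(c("mpb", "bpc"), "TO", g)), 0, row[[3]]))
  }

  ## ---- absolute bounds (reconstructed magnitudes) ----------------------
  B <- params$biomass
  per_lt <- 1 / params$lt_per_day

  ## meiofauna & nematode respiration from O2-based specific rates
  for (g in c("mfb", "nem")) {
    r <- params$meio_resp_rate * params$emersion_h * B[[g]]
    add(le(cset(paste0(g, "TOres"), -1), -r[1], paste0("abs_resp_", g, "_lo")))
    add(le(cset(paste0(g, "TOres"), 1), r[2], paste0("abs_resp_", g, "_up")))
  }
  ## meiofauna & nematode total ingestion
  for (g in c("mfb", "nem")) {
    rate <- if (g == "nem") params$nem_ingest_rate else params$mfb_ingest_rate
    C <- food_in(g)
    add(le(cset(C, -1), -rate[1] * B[[g]], paste0("abs_cons_", g, "_lo")))
    add(le(cset(C, 1), rate[2] * B[[g]], paste0("abs_cons_", g, "_up")))
  }
  ## macrofauna: consumption from production (P/B and P/C), respiration
  ## from mass-specific rates, imports from production availability
  for (g in mac) {
    CI <- c(food_in(g), paste0("impTO", g))
    lo <- B[[g]] * params$pb_range[1] / params$pc_max * per_lt
    hi <- B[[g]] * params$pb_range[2] / params$pc_min
    add(le(cset(CI, -1), -lo, paste0("abs_cons_", g, "_lo")))
    add(le(cset(CI, 1), hi, paste0("abs_cons_", g, "_up")))
    r <- B[[g]] * params$mac_resp_rate * per_lt
    add(le(cset(paste0(g, "TOres"), -1), -r[1], paste0("abs_resp_", g, "_lo")))
    add(le(cset(paste0(g, "TOres"), 1), r[2], paste0("abs_resp_", g, "_up")))
    imp <- B[[g]] * params$pb_range * params$import_frac
    add(le(cset(paste0("impTO", g), -1), -imp[1], paste0("abs_imp_", g, "_lo")))
    add(le(cset(paste0("impTO", g), 1), imp[2], paste0("abs_imp_", g, "_up")))
  }

  ## shorebirds (winter only): consumption, respiration and egestion from
  ## the energy budget C = n * 3 * BMR / AE at the two density scenarios
  if (winter) {
    Cin <- food_in("cbr")
    cb <- bird_consumption_bound(params$bird_density, params$bird_bmr,
                                 params$bird_ae) * per_lt
    add(le(cset(Cin, -1), -cb[1], "abs_cons_cbr_lo"))
    add(le(cset(Cin, 1), cb[2], "abs_cons_cbr_up"))
    rb <- params$bird_density * params$bird_bmr * per_lt
    add(le(c(cbrTOres = -1), -rb[1], "abs_resp_cbr_lo"))
    add(le(c(cbrTOres = 1), rb[2], "abs_resp_cbr_up"))
    eg <- (1 - params$bird_ae) * cb
    add(le(c(cbrTObpc = -1), -eg[1], "abs_egest_cbr_lo"))
    add(le(c(cbrTObpc = 1), eg[2], "abs_egest_cbr_up"))
    ## deposit feeders dominate the bird diet (Hydrobia-based diets)
    share <- params$bird_dep_diet_min
    add(le(c(cset(setdiff(Cin, "depTOcbr"), share),
             cset("depTOcbr", share - 1)), 0, "cbr_diet_dep_min"))
  }

  lim_problem(comp, flows, brouage_measured_values(season), con,
              season = season)
}

#' Path to a bundled model or data file
#' @param file file name under the package's `extdata`.
#' @return absolute path.
#' @export
tideweb_file <- function(file) {
  out <- system.file("extdata", file, package = "tideweb", mustWork = FALSE)
  if (!nzchar(out)) stop("bundled file not found: ", file)
  out
}
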