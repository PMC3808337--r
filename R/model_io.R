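#' @importFrom stats rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

# Reserved boundary tokens.  Sources: gpp (gross primary production), imp
# (import from outside the low-tide window).  Sinks: res (respiration),
# exp (export), ext (external loss).
BOUNDARY_SOURCES <- c("gpp", "imp")
BOUNDARY_SINKS   <- c("res", "exp", "ext")

#' Split a flow code into source and sink
#'
#' Flow codes are case-sensitive 8-character strings `xxxTOyyy`: a
#' three-letter source, the literal `TO`, and a three-letter sink.  Sources
#' and sinks are compartment abbreviations or the reserved boundary tokens
#' `gpp`/`imp` (sources) and `res`/`exp`/`ext` (sinks).
#'
#' @param code character vector of flow codes.
#' @return data.frame with columns `code`, `source`, `sink`.
#' @examples
#' flow_ends("mpbTOmfb")
#' @export
flow_ends <- function(code) {
  ok <- grepl("^[a-z]{3}TO[a-z]{3}$", code)
  if (!all(ok)) {
    stop("malformed flow code(s): ", paste(code[!ok], collapse = ", "),
         " (expected 'xxxTOyyy', lower-case 3-letter ends)")
  }
  src <- substr(code, 1, 3)
  snk <- substr(code, 6, 8)
  if (any(bad <- src == snk)) {
    stop("flow code with identical source and sink: ",
         paste(code[bad], collapse = ", "))
  }
  data.frame(code = code, source = src, sink = snk,
             stringsAsFactors = FALSE)
}

#' Construct a compartment table
#'
#' @param abbrev three-letter compartment codes (unique).
#' @param name free-text names.
#' @param living logical; is the compartment alive?
#' @param nonliving_pool logical; is it a detrital carbon pool?  Implies
#'   `living = FALSE`.
#' @return data.frame of class `tw_compartments`.
#' @export
compartment_table <- function(abbrev, name = abbrev, living = TRUE,
                              nonliving_pool = FALSE) {
  stopifnot(!anyDuplicated(abbrev), all(nchar(abbrev) == 3L))
  living <- rep_len(living, length(abbrev))
  nonliving_pool <- rep_len(nonliving_pool, length(abbrev))
  if (any(nonliving_pool & living))
    stop("a non-living pool cannot be flagged living")
  if (any(abbrev %in% c(BOUNDARY_SOURCES, BOUNDARY_SINKS)))
    stop("compartment abbreviation clashes with a reserved boundary token")
  out <- data.frame(abbrev = abbrev, name = rep_len(name, length(abbrev)),
                    living = living, nonliving_pool = nonliving_pool,
                    stringsAsFactors = FALSE)
  class(out) <- c("tw_compartments", "data.frame")
  out
}

#' Assemble a linear inverse model (LIM) problem
#'
#' Builds the equality system `A x = b` (one mass-balance row per
#' compartment, generated from the flow topology, plus any measured-flow
#' rows) and the inequality system `G x >= h` (declared constraints plus
#' one non-negativity row per flow).
#'
#' @param compartments a [compartment_table()].
#' @param flows character vector of flow codes (the variable ordering).
#' @param measured list of measured equality rows; each element is
#'   `list(coef = c(code = coefficient, ...), value = number, label = ...)`.
#'   A plain named numeric vector `c(code = value)` is also accepted and
#'   fixes single flows.
#' @param constraints list of inequality rows; each element is
#'   `list(coef = c(code = coefficient, ...), dir = "<="|">=",
#'   rhs = number, label = ...)`.
#' @param season optional season tag (free text).
#' @return object of class `lim_problem` with elements `flows`,
#'   `compartments`, `A`, `b`, `G`, `h`, `season`.
#' @export
lim_problem <- function(compartments, flows, measured = list(),
                        constraints = list(), season = NULL) {
  ends <- flow_ends(flows)
  if (anyDuplicated(flows))
    stop("duplicate flow code(s): ",
         paste(unique(flows[duplicated(flows)]), collapse = ", "))
  known <- c(compartments$abbrev, BOUNDARY_SOURCES, BOUNDARY_SINKS)
  bad <- setdiff(unique(c(ends$source, ends$sink)), known)
  if (length(bad))
    stop("flow code references undeclared compartment(s): ",
         paste(bad, collapse = ", "))
  if (any(ends$source %in% BOUNDARY_SINKS))
    stop("boundary sink token used as a source")
  if (any(ends$sink %in% BOUNDARY_SOURCES))
    stop("boundary source token used as a sink")

  n <- length(flows)
  row_matrix <- function(lst, labels) {
    if (!length(lst)) return(matrix(0, 0L, n, dimnames = list(NULL, flows)))
    matrix(as.numeric(unlist(lst, use.names = FALSE)), ncol = n,
           byrow = TRUE, dimnames = list(labels, flows))
  }
  # Mass balances: +1 for every inflow, -1 for every outflow, b = 0.
  A_bal <- row_matrix(lapply(compartments$abbrev, function(cp) {
    (ends$sink == cp) - (ends$source == cp)
  }), paste0("balance_", compartments$abbrev))
  b_bal <- rep(0, nrow(A_bal))

  norm_row <- function(m, what) {
    if (is.numeric(m) && !is.list(m) && !is.null(names(m)) &&
        length(m) == 1L && is.null(attr(m, "coef"))) {
      m <- list(coef = setNames(1, names(m)), value = unname(m),
                label = names(m))
    }
    if (is.null(m$label)) m$label <- paste(names(m$coef), collapse = "+")
    unknown <- setdiff(names(m$coef), flows)
    if (length(unknown))
      stop(what, " row '", m$label, "' references undeclared flow(s): ",
           paste(unknown, collapse = ", "))
    m
  }

  measured <- lapply(measured, norm_row, what = "measured")
  A_meas <- row_matrix(lapply(measured, function(m) {
    row <- setNames(numeric(n), flows); row[names(m$coef)] <- m$coef; row
  }), vapply(measured, `[[`, "", "label"))
  b_meas <- vapply(measured, function(m) as.numeric(m$value), 0)

  constraints <- lapply(constraints, norm_row, what = "constraint")
  G_con <- row_matrix(lapply(constraints, function(m) {
    row <- setNames(numeric(n), flows); row[names(m$coef)] <- m$coef
    if (identical(m$dir, "<=")) row <- -row
    else if (!identical(m$dir, ">=")) stop("constraint dir must be <= or >=")
    row
  }), vapply(constraints, `[[`, "", "label"))
  h_con <- vapply(constraints, function(m) {
    v <- as.numeric(m$rhs); if (identical(m$dir, "<=")) -v else v
  }, 0)

  G_pos <- diag(n)
  dimnames(G_pos) <- list(paste0("nonneg_", flows), flows)

  structure(list(
    flows = flows,
    compartments = compartments,
    A = rbind(A_bal, A_meas), b = c(b_bal, b_meas),
    G = rbind(G_con, G_pos), h = c(h_con, rep(0, n)),
    n_balances = nrow(A_bal),
    measured = measured, constraints = constraints,
    season = season
  ), class = "lim_problem")
}

#' Construct a LIM problem from raw constraint matrices
#'
#' Low-level constructor for abstract flow polytopes `{A x = b, G x >= h}`
#' that are not compartment mass-balance models (test polytopes, reduced
#' examples).  No balance rows are generated; non-negativity rows are
#' appended unless disabled.
#'
#' @param flows variable names.
#' @param A,b equality system (may have zero rows).
#' @param G,h inequality system in `G x >= h` orientation.
#' @param nonneg append one `x_i >= 0` row per variable.
#' @return object of class `lim_problem` with an empty compartment table.
#' @export
raw_lim_problem <- function(flows, A = NULL, b = numeric(0), G = NULL,
                            h = numeric(0), nonneg = TRUE) {
  n <- length(flows)
  if (is.null(A)) A <- matrix(0, 0L, n)
  if (is.null(G)) G <- matrix(0, 0L, n)
  A <- as.matrix(A); G <- as.matrix(G)
  stopifnot(ncol(A) == n, ncol(G) == n,
            nrow(A) == length(b), nrow(G) == length(h))
  colnames(A) <- flows; colnames(G) <- flows
  if (nonneg) {
    G_pos <- diag(n)
    dimnames(G_pos) <- list(paste0("nonneg_", flows), flows)
    G <- rbind(G, G_pos); h <- c(h, rep(0, n))
  }
  structure(list(flows = flows,
                 compartments = compartment_table(character(0)),
                 A = A, b = b, G = G, h = h,
                 n_balances = 0L, measured = list(), constraints = list(),
                 season = NULL),
            class = "lim_problem")
}

#' @export
print.lim_problem <- function(x, ...) {
  cat("Linear inverse model",
      if (!is.null(x$season)) paste0("(", x$season, ")"), "\n")
  cat("  compartments:", nrow(x$compartments),
      sprintf("(%d living, %d pools)", sum(x$compartments$living),
              sum(x$compartments$nonliving_pool)), "\n")
  cat("  flows:       ", length(x$flows), "\n")
  cat("  equalities:  ", nrow(x$A),
      sprintf("(%d balances, %d measured)", x$n_balances,
              nrow(x$A) - x$n_balances), "\n")
  cat("  inequalities:", nrow(x$G),
      sprintf("(%d constraints, %d non-negativity)",
              nrow(x$G) - length(x$flows), length(x$flows)), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------
## Declaration format
##
## Plain-text sections:
##   SEASON <tag>                (optional)
##   COMPARTMENTS                abbrev  name ...  living|dead|pool
##   FLOWS                       one code per line
##   MEASURED                    linear expression = value
##   CONSTRAINTS                 linear expression <= / >= value
## '#' starts a comment; blank lines ignored.
## ---------------------------------------------------------------------

parse_linear_expr <- function(txt, line) {
  s <- gsub("[[:space:]]+", "", txt)
  s <- gsub("+-", "-", s, fixed = TRUE)
  if (s == "") stop("empty linear expression on line: ", line)
  # split keeping signs: insert separator before each +/- not in an exponent
  s <- gsub("([^eE])([+-])", "\\1;\\2", s)
  terms <- strsplit(s, ";", fixed = TRUE)[[1]]
  terms <- terms[nzchar(terms)]
  coef <- numeric(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec(
      "^([+-]?)(([0-9.]+([eE][+-]?[0-9]+)?)\\*)?([a-z]{3}TO[a-z]{3})$", tm))[[1]]
    if (!length(m))
      stop("cannot parse term '", tm, "' in line: ", line)
    k <- if (m[4] == "") 1 else as.numeric(m[4])
    if (m[2] == "-") k <- -k
    code <- m[6]
    coef[code] <- if (code %in% names(coef)) coef[[code]] + k else k
  }
  coef
}

#' Parse a LIM declaration document
#'
#' @param text character scalar (whole document) or vector of lines.
#' @return a [lim_problem()].
#' @seealso [read_lim()], [write_lim()], [format_lim()]
#' @export
parse_lim <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  season <- NULL
  section <- NA_character_
  comp <- list(); flows <- character(0)
  measured <- list(); constraints <- list()

  for (ln in lines) {
    up <- toupper(ln)
    if (grepl("^SEASON\\b", up)) { season <- trimws(sub("^SEASON", "", ln)); next }
    if (up %in% c("COMPARTMENTS", "FLOWS", "MEASURED", "CONSTRAINTS")) {
      section <- up; next
    }
    if (identical(up, "END")) break
    if (is.na(section)) stop("content before any section header: ", ln)
    switch(section,
      COMPARTMENTS = {
        toks <- strsplit(ln, "[[:space:]]+")[[1]]
        if (length(toks) < 2L) stop("bad compartment line: ", ln)
        flag <- tolower(toks[length(toks)])
        if (!flag %in% c("living", "dead", "pool"))
          stop("compartment flag must be living|dead|pool: ", ln)
        nm <- if (length(toks) > 2L)
          paste(toks[2:(length(toks) - 1L)], collapse = " ") else toks[1]
        comp[[length(comp) + 1L]] <- list(abbrev = toks[1], name = nm,
                                          living = flag == "living",
                                          pool = flag == "pool")
      },
      FLOWS = {
        flows <- c(flows, strsplit(ln, "[[:space:]]+")[[1]])
      },
      MEASURED = {
        parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(parts) != 2L) stop("bad measured line: ", ln)
        measured[[length(measured) + 1L]] <- list(
          coef = parse_linear_expr(parts[1], ln),
          value = as.numeric(parts[2]),
          label = trimws(parts[1]))
      },
      CONSTRAINTS = {
        dir <- if (grepl("<=", ln, fixed = TRUE)) "<="
               else if (grepl(">=", ln, fixed = TRUE)) ">="
               else stop("constraint needs <= or >=: ", ln)
        parts <- strsplit(ln, dir, fixed = TRUE)[[1]]
        if (length(parts) != 2L) stop("bad constraint line: ", ln)
        constraints[[length(constraints) + 1L]] <- list(
          coef = parse_linear_expr(parts[1], ln),
          dir = dir, rhs = as.numeric(parts[2]),
          label = trimws(ln))
      })
  }
  cmp <- compartment_table(
    abbrev = vapply(comp, `[[`, "", "abbrev"),
    name   = vapply(comp, `[[`, "", "name"),
    living = vapply(comp, `[[`, TRUE, "living"),
    nonliving_pool = vapply(comp, `[[`, TRUE, "pool"))
  lim_problem(cmp, flows, measured, constraints, season = season)
}

#' Read a LIM declaration file
#' @param path file path.
#' @return a [lim_problem()].
#' @export
read_lim <- function(path) parse_lim(readLines(path, warn = FALSE))

fmt_num <- function(x) {
  # shortest decimal representation that round-trips a double
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

fmt_expr <- function(coef) {
  parts <- character(0)
  for (i in seq_along(coef)) {
    k <- coef[[i]]; code <- names(coef)[i]
    term <- if (k == 1) code
            else if (k == -1) paste0("-", code)
            else paste0(fmt_num(k), "*", code)
    if (i > 1L && !startsWith(term, "-")) term <- paste0("+ ", term)
    else if (i > 1L) term <- paste0("- ", sub("^-", "", term))
    parts <- c(parts, term)
  }
  paste(parts, collapse = " ")
}

#' Serialize a LIM problem to the declaration format
#' @param p a [lim_problem()].
#' @return character vector of lines.
#' @export
format_lim <- function(p) {
  stopifnot(inherits(p, "lim_problem"))
  out <- character(0)
  if (!is.null(p$season)) out <- c(out, paste("SEASON", p$season))
  out <- c(out, "COMPARTMENTS")
  flag <- ifelse(p$compartments$nonliving_pool, "pool",
                 ifelse(p$compartments$living, "living", "dead"))
  out <- c(out, sprintf("%s  %s  %s", p$compartments$abbrev,
                        p$compartments$name, flag))
  out <- c(out, "FLOWS", p$flows, "MEASURED")
  out <- c(out, vapply(p$measured, function(m)
    paste(fmt_expr(m$coef), "=", fmt_num(m$value)), ""))
  out <- c(out, "CONSTRAINTS")
  out <- c(out, vapply(p$constraints, function(m)
    paste(fmt_expr(m$coef), m$dir, fmt_num(m$rhs)), ""))
  c(out, "END")
}

#' Write a LIM problem to a declaration file
#' @param p a [lim_problem()].
#' @param path file path.
#' @param header optional comment lines (written with a leading '#').
#' @return `path`, invisibly.
#' @export
write_lim <- function(p, path, header = NULL) {
  lines <- format_lim(p)
  if (!is.null(header)) lines <- c(paste("#", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write a flow network in SCOR exchange format
#'
#' The legacy Ulanowicz exchange format: a title line; compartment and
#' living counts; compartment names; then biomass, import, export,
#' respiration records (`i value`) and flow records (`i j value`), each
#' section terminated by a `-1` line.
#'
#' @param net a [flow_network()].
#' @param path file path.
#' @param title title line.
#' @param biomass optional per-compartment biomasses.
#' @return `path`, invisibly.
#' @export
write_scor <- function(net, path, title = "flow network", biomass = NULL) {
  stopifnot(inherits(net, "flow_network"))
  cmp <- net$compartments
  # SCOR expects living compartments listed first
  ord <- order(!cmp$living)
  cmp <- cmp[ord, , drop = FALSE]
  Tm <- net$T[ord, ord, drop = FALSE]
  z <- net$z[ord]; e <- net$e[ord]; r <- net$r[ord]
  if (is.null(biomass)) biomass <- rep(0, nrow(cmp))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("%d %d", nrow(cmp), sum(cmp$living)), con)
  writeLines(cmp$abbrev, con)
  sec <- function(val) {
    idx <- which(val != 0)
    writeLines(c(sprintf("%d %.10g", idx, val[idx]), "-1"), con)
  }
  sec(biomass); sec(z); sec(e); sec(r)
  idx <- which(Tm != 0, arr.ind = TRUE)
  writeLines(c(sprintf("%d %d %.10g", idx[, 1], idx[, 2],
                       Tm[idx]), "-1"), con)
  invisible(path)
}
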