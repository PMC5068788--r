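# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
.MONOISOTOPIC <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, P = 30.97376163, S = 31.97207100)
.PROTON_MASS <- 1.007276

#' Monoisotopic mass of a molecular formula
#'
#' Parses formulas over C, H, N, O, P, S (e.g. `"C6H6O2"`) and sums the
#' monoisotopic atomic masses.
#'
#' @param formula character vector of formulas.
#' @return numeric vector of monoisotopic masses in Da (`NA` for empty or
#'   missing formulas).
#' @examples
#' formula_mass("C6H6O2")  # muconic dialdehyde, 110.0368 Da
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    if (!nzchar(f) || sum(nchar(parts)) != nchar(f))
      stop("unparseable formula: '", f, "'")
    total <- 0
    for (pt in parts) {
      el <- gsub("[0-9]", "", pt)
      cnt <- gsub("[^0-9]", "", pt)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(.MONOISOTOPIC))
        stop("unsupported element '", el, "' in formula '", f, "'")
      total <- total + .MONOISOTOPIC[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Theoretical adduct m/z from a neutral monoisotopic mass
#'
#' Supports the two ESI adducts used here: `[M+H]+` adds and `[M-H]-`
#' subtracts one proton (1.007276 Da; the electron mass is neglected).
#'
#' @param neutral_mass neutral monoisotopic mass in Da.
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @return theoretical m/z.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (!all(adduct %in% c("[M+H]+", "[M-H]-")))
    stop("unsupported adduct: ",
         paste(setdiff(adduct, c("[M+H]+", "[M-H]-")), collapse = ", "))
  if (any(adduct == "[M-H]-" & neutral_mass <= .PROTON_MASS))
    stop("neutral mass must exceed the proton mass for [M-H]-")
  neutral_mass + ifelse(adduct == "[M+H]+", .PROTON_MASS, -.PROTON_MASS)
}

#' Signed mass error in parts per million
#'
#' @param observed_mz observed m/z.
#' @param theoretical_mz theoretical m/z (> 0).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

#' Load a compound reference table
#'
#' Reads a CSV with columns `name`, `formula`, `class`, `fragments`
#' (semicolon-separated fragment m/z) and computes monoisotopic masses from
#' the formulas. Without a path, the small bundled table of the putative
#' amniotic-fluid metabolites is loaded; entries known only at the
#' metabolite-class level carry no formula and are skipped by mass matching.
#'
#' @param path optional CSV path; default: the bundled table.
#' @return data.frame with an added `monoisotopic_mass` column.
#' @export
compound_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compounds.csv", package = "ocplsda")
  ct <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("name", "formula", "class", "fragments")
  if (!all(need %in% names(ct)))
    stop("compound table must have columns: ", paste(need, collapse = ", "))
  ct$monoisotopic_mass <- formula_mass(ct$formula)
  if (any(!is.na(ct$monoisotopic_mass) & ct$monoisotopic_mass <= 0))
    stop("nonpositive monoisotopic mass in compound table")
  ct
}

#' Match observed feature m/z against a compound table
#'
#' For each feature, candidate compounds are those whose adduct-appropriate
#' theoretical m/z ( `[M-H]-` in negative mode, `[M+H]+` in positive mode)
#' lies within the ppm tolerance. Matches are ordered by absolute ppm error,
#' then name.
#'
#' @param features data.frame with columns `feature_id`, `mz`, `mode`
#'   (`"negative"` or `"positive"`).
#' @param compounds a [compound_table()]-style data.frame.
#' @param tolerance_ppm match tolerance (default 10 ppm).
#' @return data.frame with one row per (feature, candidate) match: columns
#'   `feature_id`, `observed_mz`, `adduct`, `name`, `class`,
#'   `theoretical_mz`, `mass_error_ppm`, `fragments`.
#' @export
match_features <- function(features, compounds = compound_table(),
                           tolerance_ppm = 10) {
  if (tolerance_ppm <= 0) stop("tolerance must be positive")
  if (is.null(compounds) || nrow(compounds) == 0)
    stop("empty compound table")
  stopifnot(all(c("feature_id", "mz", "mode") %in% names(features)))
  if (!all(features$mode %in% c("negative", "positive")))
    stop("mode must be 'negative' or 'positive'")
  usable <- !is.na(compounds$monoisotopic_mass)
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    adduct <- if (features$mode[i] == "negative") "[M-H]-" else "[M+H]+"
    theo <- adduct_mz(compounds$monoisotopic_mass[usable], adduct)
    ppm <- ppm_error(features$mz[i], theo)
    hit <- which(abs(ppm) <= tolerance_ppm)
    if (!length(hit)) next
    df <- data.frame(feature_id = features$feature_id[i],
                     observed_mz = features$mz[i], adduct = adduct,
                     name = compounds$name[usable][hit],
                     class = compounds$class[usable][hit],
                     theoretical_mz = theo[hit], mass_error_ppm = ppm[hit],
                     fragments = compounds$fragments[usable][hit],
                     stringsAsFactors = FALSE)
    out[[i]] <- df[order(abs(df$mass_error_ppm), df$name), ]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(feature_id = character(), observed_mz = numeric(),
                      adduct = character(), name = character(),
                      class = character(), theoretical_mz = numeric(),
                      mass_error_ppm = numeric(), fragments = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Split RT_mz feature identifiers into retention time and m/z
#'
#' @param feature_ids character vector like `"5.06_197.0808"`.
#' @return data.frame with `feature_id`, `rt`, `mz`.
#' @export
parse_feature_ids <- function(feature_ids) {
  parts <- strsplit(feature_ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("feature id(s) not in RT_mz form: ",
         paste(utils::head(feature_ids[bad], 3), collapse = ", "))
  data.frame(feature_id = feature_ids,
             rt = as.numeric(vapply(parts, `[[`, character(1), 1)),
             mz = as.numeric(vapply(parts, `[[`, character(1), 2)),
             stringsAsFactors = FALSE)
}
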