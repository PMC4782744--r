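#' Read spectra from CSV
#'
#' Two plain-text dialects are supported. The *wide* dialect has a first
#' column `wavelength_nm` and one column per measurement point; optional
#' leading rows whose first cell is `label` or `tooth` carry the
#' per-point diagnosis and tooth id. The *long* dialect has columns
#' `point_id`, `wavelength_nm`, `intensity` and optionally `label` and
#' `tooth_id`. Labels may instead be supplied through a companion table
#' (CSV with columns `point_id`, `tooth_id`, `label`) via `labels`.
#'
#' All points must share one wavelength grid; a point measured on a
#' different grid is a hard error naming the offending point. Rows are
#' sorted by wavelength on read.
#'
#' @param path path to the spectra CSV.
#' @param format `"wide"` or `"long"`.
#' @param labels optional path to a labels CSV, or a data frame with
#'   columns `point_id`, `label` and optionally `tooth_id`. Inline labels
#'   in the spectra file take precedence.
#' @return a [drs_dataset()].
#' @export
read_spectra <- function(path, format = c("wide", "long"), labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  label_tab <- read_label_table(labels)
  if (format == "wide") read_spectra_wide(path, label_tab)
  else read_spectra_long(path, label_tab)
}

read_label_table <- function(labels) {
  if (is.null(labels)) return(NULL)
  tab <- if (is.data.frame(labels)) labels else
    utils::read.csv(labels, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("point_id", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("label table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(tab$tooth_id)) tab$tooth_id <- "t?"
  tab
}

read_spectra_wide <- function(path, label_tab) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (names(raw)[1L] != "wavelength_nm") {
    stop("wide spectra CSV must start with a 'wavelength_nm' column",
         call. = FALSE)
  }
  point_id <- names(raw)[-1L]
  key <- raw[[1L]]
  inline_label <- if (any(key == "label")) {
    unlist(raw[match("label", key), -1L], use.names = FALSE)
  } else NULL
  inline_tooth <- if (any(key == "tooth")) {
    unlist(raw[match("tooth", key), -1L], use.names = FALSE)
  } else NULL
  num <- raw[!key %in% c("label", "tooth"), , drop = FALSE]
  w <- suppressWarnings(as.numeric(num[[1L]]))
  if (anyNA(w)) stop("non-numeric wavelength rows in wide CSV", call. = FALSE)
  ord <- order(w)
  intens <- vapply(num[-1L], function(col) as.numeric(col),
                   numeric(nrow(num)))[ord, , drop = FALSE]
  assemble_dataset(w[ord], intens, point_id, inline_label, inline_tooth,
                   label_tab)
}

read_spectra_long <- function(path, label_tab) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("point_id", "wavelength_nm", "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("long spectra CSV lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  point_id <- unique(tab$point_id)
  pieces <- split(tab, factor(tab$point_id, levels = point_id))
  ref <- sort(pieces[[1L]]$wavelength_nm)
  intens <- matrix(NA_real_, length(ref), length(pieces))
  for (i in seq_along(pieces)) {
    p <- pieces[[i]][order(pieces[[i]]$wavelength_nm), , drop = FALSE]
    if (length(p$wavelength_nm) != length(ref) ||
        any(p$wavelength_nm != ref)) {
      stop(sprintf("point '%s' is measured on a different wavelength grid",
                   point_id[i]), call. = FALSE)
    }
    intens[, i] <- p$intensity
  }
  inline_label <- if (!is.null(tab$label)) {
    vapply(pieces, function(p) as.character(p$label[1L]), character(1L))
  } else NULL
  inline_tooth <- if (!is.null(tab$tooth_id)) {
    vapply(pieces, function(p) as.character(p$tooth_id[1L]), character(1L))
  } else NULL
  assemble_dataset(ref, intens, point_id, inline_label, inline_tooth,
                   label_tab)
}

assemble_dataset <- function(w, intens, point_id, inline_label, inline_tooth,
                             label_tab) {
  lab <- inline_label
  tooth <- inline_tooth
  if (!is.null(label_tab)) {
    idx <- match(point_id, label_tab$point_id)
    if (anyNA(idx)) {
      stop(sprintf("label table misses point(s): %s",
                   paste(point_id[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    if (is.null(lab)) lab <- label_tab$label[idx]
    if (is.null(tooth)) tooth <- label_tab$tooth_id[idx]
  }
  if (is.null(lab)) {
    stop("no labels: provide inline labels or a companion label table",
         call. = FALSE)
  }
  drs_dataset(wavelength_grid(w), intens, lab,
              point_id = point_id, tooth_id = tooth)
}

#' Write spectra to CSV
#'
#' Writes the wide or long dialect read by [read_spectra()], with labels
#' and tooth ids inline. Wavelengths are stored to 4 decimal places (nm),
#' intensities at full double precision, so a write/read round trip is
#' exact at the stored precision.
#'
#' @param data a [drs_dataset()].
#' @param path output path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(data, path, format = c("wide", "long")) {
  stopifnot(inherits(data, "drs_dataset"))
  format <- match.arg(format)
  w <- sprintf("%.4f", unclass(data$grid))
  s <- data$samples
  if (format == "wide") {
    lines <- c(
      paste(c("wavelength_nm", s$point_id), collapse = ","),
      paste(c("label", as.character(s$label)), collapse = ","),
      paste(c("tooth", s$tooth_id), collapse = ","),
      vapply(seq_along(w), function(i) {
        paste(c(w[i], sprintf("%.17g", data$intensities[i, ])), collapse = ",")
      }, character(1L))
    )
  } else {
    lines <- "point_id,tooth_id,label,wavelength_nm,intensity"
    for (j in seq_len(nrow(s))) {
      lines <- c(lines, sprintf(
        "%s,%s,%s,%s,%.17g",
        s$point_id[j], s$tooth_id[j], as.character(s$label[j]),
        w, data$intensities[, j]
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Rule-set serialization
#'
#' Rule sets are stored as a self-describing key/value text document with
#' an explicit schema version, e.g.
#' \preformatted{
#' schema: drs-ruleset/1
#' n_rules: 1
#' rule.1.channel: 1422
#' rule.1.wavelength_nm: 791.0000
#' rule.1.threshold: 0.3255
#' rule.1.direction: at_least
#' }
#' `read_ruleset(write_ruleset(r))` reproduces `r` field for field.
#'
#' @param rules a [rule_set()].
#' @param path file path.
#' @return `write_ruleset()` returns `path` invisibly; `read_ruleset()`
#'   returns a [rule_set()].
#' @export
write_ruleset <- function(rules, path) {
  rules <- as_rule_set(rules)
  lines <- c("schema: drs-ruleset/1",
             sprintf("n_rules: %d", length(rules)))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    lines <- c(lines,
      sprintf("rule.%d.channel: %d", i, r$channel),
      sprintf("rule.%d.wavelength_nm: %s", i,
              if (is.na(r$wavelength_nm)) "NA" else
                sprintf("%.4f", r$wavelength_nm)),
      sprintf("rule.%d.threshold: %.17g", i, r$threshold),
      sprintf("rule.%d.direction: %s", i, r$direction))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  kv <- read_kv(path)
  if (!identical(kv[["schema"]], "drs-ruleset/1")) {
    stop("not a drs-ruleset/1 document (missing fields: schema)", call. = FALSE)
  }
  if (is.null(kv[["n_rules"]])) {
    stop("malformed rule-set document (missing fields: n_rules)", call. = FALSE)
  }
  n <- as.integer(kv[["n_rules"]])
  rules <- vector("list", n)
  for (i in seq_len(n)) {
    need <- sprintf("rule.%d.%s", i,
                    c("channel", "wavelength_nm", "threshold", "direction"))
    miss <- need[!need %in% names(kv)]
    if (length(miss)) {
      stop(sprintf("malformed rule-set document (missing fields: %s)",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    wl <- kv[[need[2L]]]
    rules[[i]] <- threshold_rule(
      channel = as.integer(kv[[need[1L]]]),
      threshold = as.numeric(kv[[need[3L]]]),
      direction = kv[[need[4L]]],
      wavelength_nm = if (identical(wl, "NA")) NA_real_ else as.numeric(wl)
    )
  }
  rule_set(rules)
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad)) {
    stop(sprintf("malformed key/value line: '%s'", lines[bad][1L]),
         call. = FALSE)
  }
  stats::setNames(
    lapply(m, function(x) x[3L]),
    vapply(m, function(x) trimws(x[2L]), character(1L))
  )
}
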