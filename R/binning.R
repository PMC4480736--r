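#' Discretize evidence values into bins
#'
#' Each evidence type is discretized with a scheme suited to its intrinsic
#' character: co-expression into equal-width correlation bins over
#' `[-1, 1]`; interolog support into one bin per species count; DDI into
#' one bin per confidence grade plus a level-0 bin; smallest shared
#' biological process into log2-spaced size bins plus a dedicated
#' "no shared term" bin. Missing values receive no bin (`NA`).
#'
#' The scheme is built once, from the full candidate universe of values,
#' and can then be re-applied to subsets (the gold-standard pairs) with
#' [bin_values()], so every bin that can occur downstream is represented in
#' the likelihood table.
#'
#' @param values Numeric vector of raw evidence values (`NA` = missing;
#'   `Inf` = the "no shared term" sentinel for `ssbp`).
#' @param evidence One of `"coexpr"`, `"ddi"`, `"interolog"`, `"ssbp"`.
#' @param n_coexpr_bins Number of equal-width correlation bins.
#' @return A list with `scheme` (a `ppi_binning_scheme`: evidence name, bin
#'   labels, assignment parameters) and `bins` (character bin label per
#'   value).
#' @examples
#' make_bins(c(0.95, -0.2, NA), "coexpr")$bins
#' @export
make_bins <- function(values,
                      evidence = c("coexpr", "ddi", "interolog", "ssbp"),
                      n_coexpr_bins = 10) {
  evidence <- match.arg(evidence)
  if (all(is.na(values))) {
    stop("all values for evidence '", evidence, "' are missing; ",
      "this evidence cannot be binned",
      call. = FALSE
    )
  }
  finite <- values[!is.na(values) & is.finite(values)]
  scheme <- switch(evidence,
    coexpr = {
      breaks <- seq(-1, 1, length.out = n_coexpr_bins + 1)
      labels <- paste0(
        "(", sprintf("%.2f", breaks[-length(breaks)]),
        ",", sprintf("%.2f", breaks[-1]), "]"
      )
      list(evidence = evidence, type = "interval", breaks = breaks,
        labels = labels)
    },
    ddi = {
      levels <- 0:max(finite, 0)
      list(evidence = evidence, type = "category",
        values = levels, labels = paste0("L", levels))
    },
    interolog = {
      counts <- 0:max(finite, 0)
      list(evidence = evidence, type = "category",
        values = counts, labels = paste0("S", counts))
    },
    ssbp = {
      top <- max(c(finite, 2))
      breaks <- 2^(1:max(1, ceiling(log2(top))))
      breaks[length(breaks)] <- Inf
      lo <- c(2, breaks[-length(breaks)] + 1)
      labels <- ifelse(
        is.infinite(breaks),
        paste0("[", lo, ",Inf)"),
        ifelse(lo == breaks, paste0("[", lo, "]"),
          paste0("[", lo, ",", breaks, "]")
        )
      )
      list(evidence = evidence, type = "ssbp", breaks = breaks,
        labels = c(labels, "none"))
    }
  )
  class(scheme) <- "ppi_binning_scheme"
  list(scheme = scheme, bins = bin_values(values, scheme))
}

#' @rdname make_bins
#' @param scheme A `ppi_binning_scheme` from [make_bins()].
#' @export
bin_values <- function(values, scheme) {
  stopifnot(inherits(scheme, "ppi_binning_scheme"))
  out <- rep(NA_character_, length(values))
  ok <- !is.na(values)
  if (!any(ok)) {
    return(out)
  }
  if (scheme$type == "interval") {
    idx <- findInterval(values[ok], scheme$breaks,
      left.open = TRUE, rightmost.closed = FALSE
    )
    # values exactly at the lower bound fall into the first bin
    idx[values[ok] <= scheme$breaks[[1]]] <- 1L
    idx <- pmin(pmax(idx, 1L), length(scheme$labels))
    out[ok] <- scheme$labels[idx]
  } else if (scheme$type == "category") {
    m <- match(values[ok], scheme$values)
    if (anyNA(m)) {
      bad <- values[ok][is.na(m)][[1]]
      stop("value ", bad, " outside the binning scheme for evidence '",
        scheme$evidence, "'",
        call. = FALSE
      )
    }
    out[ok] <- scheme$labels[m]
  } else { # ssbp: smallest j with value <= breaks[j]; Inf sentinel -> "none"
    v <- values[ok]
    lab <- rep("none", length(v))
    fin <- is.finite(v)
    idx <- findInterval(v[fin], scheme$breaks, left.open = TRUE) + 1L
    idx <- pmin(pmax(idx, 1L), length(scheme$labels) - 1L)
    lab[fin] <- scheme$labels[idx]
    out[ok] <- lab
  }
  out
}

#' @export
print.ppi_binning_scheme <- function(x, ...) {
  cat(
    "Binning scheme for", x$evidence, "evidence:",
    length(x$labels), "bins\n "
  )
  cat(paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Bin a full evidence table
#'
#' Builds one scheme per evidence type from the supplied table (normally
#' the full candidate universe) and returns the binned table in long format
#' alongside the schemes.
#'
#' @param evidence Evidence tibble from [evidence_table()].
#' @param n_coexpr_bins Number of equal-width correlation bins.
#' @return A list with `binned` (long tibble: pair columns, `evidence`,
#'   `bin`) and `schemes` (named list of `ppi_binning_scheme`).
#' @export
bin_evidence <- function(evidence, n_coexpr_bins = 10) {
  col_of <- c(
    coexpr = "coexpr_rho", ddi = "ddi_level",
    interolog = "interolog_support", ssbp = "ssbp_size"
  )
  present <- col_of[col_of %in% names(evidence)]
  schemes <- list()
  long <- list()
  for (ev in names(present)) {
    vals <- evidence[[present[[ev]]]]
    if (all(is.na(vals))) {
      warning("evidence '", ev, "' is entirely missing and is dropped",
        call. = FALSE
      )
      next
    }
    mb <- make_bins(vals, ev, n_coexpr_bins = n_coexpr_bins)
    schemes[[ev]] <- mb$scheme
    long[[ev]] <- tibble(
      protein_a = evidence$protein_a,
      protein_b = evidence$protein_b,
      evidence = ev,
      bin = mb$bins
    ) %>% filter(!is.na(bin))
  }
  list(binned = bind_rows(long), schemes = schemes)
}
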