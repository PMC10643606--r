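#' Normalize raw plate signal to fractional cytotoxicity
#'
#' Luminescent viability signal is mapped to cytotoxicity using the plate's
#' own controls: vehicle wells define 0% cell death and a broad-spectrum
#' kill control (e.g. staurosporine) defines 100%.
#' \code{cytotoxicity = (vehicle_mean - signal)/(vehicle_mean - kill_mean)},
#' clipped to [0, 1]; replicate stacks are averaged per combination cell.
#'
#' @param raw numeric matrix (or 3-d array with replicates in the third
#'   dimension) of raw signal, doses in dimnames as in \code{dose_matrix}.
#' @param vehicle_wells numeric vector of vehicle-control signals.
#' @param kill_wells numeric vector of kill-control signals.
#' @param doses_row,doses_col dose vectors including the 0 anchor.
#' @param drug_row,drug_col drug names.
#' @return a \code{dose_matrix} on the cytotoxicity scale.
#' @export
normalize_plate <- function(raw, vehicle_wells, kill_wells,
                            doses_row, doses_col,
                            drug_row = "drugA", drug_col = "drugB") {
  stopifnot(length(vehicle_wells) >= 1, length(kill_wells) >= 1)
  v <- mean(vehicle_wells)
  k <- mean(kill_wells)
  if (v <= k)
    stop("control inversion: vehicle mean must exceed kill-control mean")
  if (length(dim(raw)) == 3L) raw <- apply(raw, c(1, 2), mean)
  cyto <- (v - raw) / (v - k)
  cyto <- pmin(pmax(cyto, 0), 1)
  structure(list(drug_row = drug_row, drug_col = drug_col,
                 doses_row = doses_row, doses_col = doses_col,
                 response = cyto),
            class = "dose_matrix")
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL on the log-dose scale,
#' \code{y = min + (max - min)/(1 + exp(-hill (log d - log ec50)))},
#' with bounds min, max in [0, 1], ec50 within the dose range widened 100x
#' each way, hill in (0, 10]. Optimization starts from a fixed grid of
#' initial values and keeps the best converged fit, so results are
#' deterministic. If no start converges (or the response is flat or runs
#' the wrong way), a flat-curve fallback (min = max = mean response) is
#' returned with \code{flat = TRUE}.
#'
#' @param doses positive dose vector (>= 4 points).
#' @param responses cytotoxicity fractions in [0, 1].
#' @return list: \code{min}, \code{max}, \code{ec50}, \code{hill},
#'   \code{flat}, \code{rss}.
#' @export
fit_4pl <- function(doses, responses) {
  stopifnot(length(doses) == length(responses))
  if (length(doses) < 4L) stop("need >= 4 dose points")
  if (any(doses <= 0)) stop("doses must be positive (drop the 0 anchor)")
  flat <- list(min = mean(responses), max = mean(responses),
               ec50 = exp(mean(log(doses))), hill = 1,
               flat = TRUE, rss = sum((responses - mean(responses))^2))
  if (stats::sd(responses) < 1e-9) return(flat)
  lo_d <- min(doses) / 100
  hi_d <- max(doses) * 100
  grid <- expand.grid(
    h = c(0.5, 1, 2, 4),
    e = exp(unname(stats::quantile(log(doses), c(0.2, 0.4, 0.6, 0.8)))))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      responses ~ lo + (hi - lo) / (1 + exp(-h * (log(doses) - log(e)))),
      start = list(lo = max(min(responses), 0), hi = min(max(responses), 1),
                   h = grid$h[i], e = grid$e[i]),
      lower = c(0, 0, 1e-3, lo_d), upper = c(1, 1, 10, hi_d),
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- stats::coef(fit)
      best <- list(min = unname(cf["lo"]), max = unname(cf["hi"]),
                   ec50 = unname(cf["e"]), hill = unname(cf["h"]),
                   flat = FALSE, rss = rss)
    }
  }
  if (is.null(best)) return(flat)
  if (best$min > best$max) return(flat)   # wrong-way (decreasing) response
  best
}

#' ZIP synergy surface of a combination dose matrix
#'
#' For every combination cell (both doses > 0), the zero-interaction
#' expectation is the Bliss-style surface of the fitted monotherapy curves,
#' \code{y_zip(a, b) = y1(a) + y2(b) - y1(a) y2(b)} on the cytotoxicity
#' scale, and the synergy score is \code{delta = observed - expected},
#' reported x100 on the percent scale (positive = synergy). The summary
#' \code{max_window_score} is the largest mean delta over any contiguous
#' 3x3 dose window (the "region of maximum synergy").
#'
#' @param dm a \code{dose_matrix}.
#' @param row_fit,col_fit monotherapy 4PL fits from \code{\link{fit_4pl}};
#'   if NULL they are fitted here from the matrix's 0-anchor row/column.
#' @param window window side length for the max-synergy region (default 3).
#' @return list of class \code{synergy_surface}: \code{delta} (percent
#'   scale, NA outside combination cells), \code{mean_delta},
#'   \code{max_window_score}, \code{max_window_coords}, the fits.
#' @export
zip_delta <- function(dm, row_fit = NULL, col_fit = NULL, window = 3L) {
  stopifnot(inherits(dm, "dose_matrix"))
  dr <- dm$doses_row
  dc <- dm$doses_col
  if (dr[1] != 0 || dc[1] != 0)
    stop("dose matrix must include the 0-dose monotherapy anchors")
  if (is.null(row_fit))
    row_fit <- fit_4pl(dr[-1], dm$response[-1, 1])
  if (is.null(col_fit))
    col_fit <- fit_4pl(dc[-1], dm$response[1, -1])
  y1 <- four_pl(dr, row_fit$min, row_fit$max, row_fit$ec50, row_fit$hill)
  y2 <- four_pl(dc, col_fit$min, col_fit$max, col_fit$ec50, col_fit$hill)
  expected <- outer(y1, y2, function(a, b) a + b - a * b)
  delta <- (dm$response - expected) * 100
  delta[1, ] <- NA
  delta[, 1] <- NA
  combo <- delta[-1, -1, drop = FALSE]
  mean_delta <- mean(combo)
  # max mean over contiguous window x window dose blocks
  nr <- nrow(combo); nc <- ncol(combo)
  w <- min(window, nr, nc)
  best <- -Inf; coords <- c(NA_integer_, NA_integer_)
  for (i in seq_len(nr - w + 1L)) {
    for (j in seq_len(nc - w + 1L)) {
      m <- mean(combo[i:(i + w - 1L), j:(j + w - 1L)])
      if (m > best) { best <- m; coords <- c(i, j) }
    }
  }
  structure(list(delta = delta, mean_delta = mean_delta,
                 max_window_score = best, max_window_coords = coords,
                 window = w, row_fit = row_fit, col_fit = col_fit),
            class = "synergy_surface")
}

#' Read / write a dose matrix CSV
#'
#' Layout: first column holds the row-drug doses, header row the column-drug
#' doses (both including the 0 anchor); cells are cytotoxicity fractions.
#'
#' @param path file path.
#' @param drug_row,drug_col drug names (not stored in the CSV).
#' @return a \code{dose_matrix}.
#' @export
read_dose_matrix <- function(path, drug_row = "drugA", drug_col = "drugB") {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        row.names = 1)
  m <- as.matrix(df)
  dr <- as.numeric(rownames(df))
  dc <- as.numeric(colnames(df))
  if (anyNA(dr) || anyNA(dc))
    stop("dose matrix row/column labels must be numeric doses")
  structure(list(drug_row = drug_row, drug_col = drug_col,
                 doses_row = dr, doses_col = dc, response = m),
            class = "dose_matrix")
}

#' @rdname read_dose_matrix
#' @param dm a \code{dose_matrix}.
#' @export
write_dose_matrix <- function(dm, path) {
  df <- as.data.frame(dm$response)
  colnames(df) <- format(dm$doses_col, trim = TRUE)
  rownames(df) <- format(dm$doses_row, trim = TRUE)
  utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Compare maximum synergy scores between two groups of combinations
#'
#' Two-sided Wilcoxon rank-sum comparison of max-synergy scores (e.g.
#' screen-nominated vs standard-of-care combinations).
#'
#' @param scores_a,scores_b numeric vectors of max synergy scores.
#' @return list: \code{median_a}, \code{median_b}, \code{p}.
#' @export
compare_synergy_groups <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) >= 1, length(scores_b) >= 1)
  list(median_a = stats::median(scores_a),
       median_b = stats::median(scores_b),
       p = rank_sum_test(scores_a, scores_b))
}
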