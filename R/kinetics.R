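# Phage adsorption and center-of-infection statistics used to validate
# screen hits: fraction of free (unadsorbed) phage over time, first-order
# adsorption rate constants, efficiency of center-of-infection formation
# (ECOI) relative to a wild-type host, and the two-tailed t comparisons
# with the star tiers used in figure legends.

#' Construct an adsorption time series
#'
#' @param time Timepoints in minutes (nonnegative, strictly increasing).
#' @param free_titer Free-phage titer (pfu/mL) in the supernatant at each
#'   timepoint.
#' @param input_titer Input titer from the mock-infection control
#'   (pfu/mL, > 0).
#' @param host_id,phage_id,replicate Labels.
#' @return An `adsorption_series` object.
#' @export
adsorption_series <- function(time, free_titer, input_titer,
                              host_id = "host", phage_id = "phage",
                              replicate = 1L) {
  stopifnot(length(time) == length(free_titer), all(time >= 0),
            all(diff(time) > 0), all(free_titer >= 0), input_titer > 0)
  structure(list(host_id = host_id, phage_id = phage_id,
                 replicate = as.integer(replicate),
                 points = data.frame(time = time, free_titer = free_titer),
                 input_titer = input_titer),
            class = "adsorption_series")
}

#' Fraction of phage left unadsorbed at a timepoint
#'
#' `free_titer(t) / input_titer`. Values above 1 can arise from plating
#' noise and are allowed but flagged with a warning. The fraction
#' adsorbed is its complement, `1 - fraction_unadsorbed`.
#'
#' @param series An [adsorption_series()].
#' @param t A recorded timepoint (minutes).
#' @return Fraction in `[0, Inf)`.
#' @export
fraction_unadsorbed <- function(series, t) {
  i <- match(t, series$points$time)
  if (is.na(i))
    stop("timepoint ", t, " not recorded (have: ",
         paste(series$points$time, collapse = ", "), ")")
  f <- series$points$free_titer[i] / series$input_titer
  if (f > 1)
    warning("fraction unadsorbed > 1 at t=", t, " (counting noise)")
  f
}

#' First-order adsorption rate constant
#'
#' Fits the classic model \eqn{\ln(P_t / P_0) = -k B t} by least squares:
#' the slope of `ln(free/input)` against time, divided by `-B`, for cell
#' density `B` (cells/mL). Timepoints with nonpositive free titer cannot
#' enter the log fit and are excluded with a warning.
#'
#' @param series An [adsorption_series()].
#' @param cell_density Host cell density `B` in cells/mL.
#' @param intercept Fit an intercept (default `TRUE`).
#' @return List with `k` (mL/min), `r_squared`, and `n_points` used.
#' @export
adsorption_rate <- function(series, cell_density, intercept = TRUE) {
  stopifnot(cell_density > 0)
  pts <- series$points
  usable <- pts$free_titer > 0
  if (any(!usable))
    warning(sum(!usable), " timepoint(s) with nonpositive free titer excluded")
  pts <- pts[usable, , drop = FALSE]
  if (nrow(pts) < 2L)
    stop("need at least 2 usable timepoints to fit an adsorption rate")
  y <- log(pts$free_titer / series$input_titer)
  fit <- if (intercept) lm(y ~ pts$time) else lm(y ~ pts$time + 0)
  slope <- coef(fit)[["pts$time"]]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(k = -slope / cell_density, r_squared = r2, n_points = nrow(pts))
}

#' Construct a center-of-infection assay record
#'
#' @param centers Plaque count from the washed, resuspended cell pellet
#'   (infected-cell centers of infection).
#' @param input_pfu Input phage count.
#' @param host_id,phage_id,replicate Labels.
#' @return An `infection_center_assay` object.
#' @export
infection_center_assay <- function(centers, input_pfu, host_id = "host",
                                   phage_id = "phage", replicate = 1L) {
  stopifnot(centers >= 0, input_pfu > 0)
  structure(list(host_id = host_id, phage_id = phage_id,
                 replicate = as.integer(replicate),
                 centers = centers, input_pfu = input_pfu),
            class = "infection_center_assay")
}

#' Efficiency of center-of-infection formation (ECOI)
#'
#' `(centers / input_pfu)` of the assay host divided by the same ratio on
#' the reference (wild-type) host; the reference against itself is 1 by
#' definition.
#'
#' @param assay,reference [infection_center_assay()]s for the same phage.
#' @return ECOI (dimensionless).
#' @export
ecoi <- function(assay, reference) {
  if (assay$phage_id != reference$phage_id)
    stop("ECOI compares the same phage on two hosts")
  if (reference$centers == 0)
    stop("reference host formed no centers of infection: ECOI undefined")
  (assay$centers / assay$input_pfu) /
    (reference$centers / reference$input_pfu)
}

#' Star label for a p-value
#'
#' The legend tiers: `***` p<0.001, `**` p<0.005, `*` p<0.05, else `ns`.
#'
#' @param p P-value.
#' @return One of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
star_label <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.005) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Two-sample two-tailed t comparison with star tiers
#'
#' Welch's unequal-variance t test by default (`var_equal = TRUE` gives
#' Student's pooled variant). Two identical constant groups are a
#' degenerate comparison: `t = 0`, `p = 1`, `"ns"`, flagged.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance Student t (default `FALSE`).
#' @return List with `t`, `p.value`, `label`, `degenerate`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs n >= 2")
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, p.value = 1, label = "ns", degenerate = TRUE))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  tt <- t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p.value = tt$p.value,
       label = star_label(tt$p.value), degenerate = FALSE)
}

#' Read tidy kinetics tables
#'
#' Adsorption TSV columns: `host_id, phage_id, replicate, time_min,
#' free_titer, input_titer`; ECOI TSV columns: `host_id, phage_id,
#' replicate, centers, input_pfu`.
#'
#' @param path TSV path.
#' @return `read_adsorption_tsv`: named list of [adsorption_series()]
#'   (one per host/phage/replicate). `read_ecoi_tsv`: named list of
#'   [infection_center_assay()].
#' @export
read_adsorption_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("host_id", "phage_id", "replicate", "time_min", "free_titer",
           "input_titer")
  if (!all(req %in% names(df)))
    stop("adsorption TSV needs columns: ", paste(req, collapse = ", "))
  sp <- split(df, paste(df$host_id, df$phage_id, df$replicate, sep = "|"))
  lapply(sp, function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    adsorption_series(d$time_min, d$free_titer, d$input_titer[1],
                      host_id = d$host_id[1], phage_id = d$phage_id[1],
                      replicate = d$replicate[1])
  })
}

#' @rdname read_adsorption_tsv
#' @export
read_ecoi_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("host_id", "phage_id", "replicate", "centers", "input_pfu")
  if (!all(req %in% names(df)))
    stop("ECOI TSV needs columns: ", paste(req, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    infection_center_assay(df$centers[i], df$input_pfu[i],
                           host_id = df$host_id[i], phage_id = df$phage_id[i],
                           replicate = df$replicate[i]))
  names(out) <- paste(df$host_id, df$phage_id, df$replicate, sep = "|")
  out
}
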