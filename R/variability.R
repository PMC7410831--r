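#' Test loops for cross-cell-type variability
#'
#' For each loop, models the log normalized interaction frequency
#' (`log(x + 1)`, since the normalized range includes 0) as a function of
#' cell type and tests against the intercept-only model:
#' \describe{
#'   \item{`lmm_lrt`}{weighted random-intercept model
#'     (`y ~ 1 + (1 | cell_type)`, maximum likelihood) against a weighted
#'     intercept-only linear model, p-value from the likelihood-ratio
#'     statistic. The default reference distribution is chi-squared with
#'     1 df, conservative for a variance component on the boundary; set
#'     `boundary_mixture = TRUE` for the 50:50 chi0/chi1 mixture.}
#'   \item{`lm_anova`}{weighted fixed-effect linear model with a cell-type
#'     factor, ANOVA F-test.}
#'   \item{`kruskal`}{Kruskal-Wallis rank test on the normalized
#'     frequencies grouped by cell type.}
#' }
#' P-values are BH-adjusted per method; loops whose model fails to
#' converge get `NA` p-values and are excluded from the adjustment (the
#' count is recorded).
#'
#' @param normM Normalized interaction matrix (tibble with id column, or
#'   matrix), as from [normalize_matrix()].
#' @param samples Sample sheet; every cell type needs >= 2 samples.
#' @param weights Optional per-observation weight matrix (from
#'   [voom_weights()]); ignored by `kruskal`.
#' @param method One of `"lmm_lrt"`, `"lm_anova"`, `"kruskal"`.
#' @param fdr BH q-value threshold defining the variable set.
#' @param boundary_mixture Use the 50:50 chi-squared mixture for the LRT.
#' @return A `loop_variability` object: tibble (`loop_id`, `statistic`,
#'   `p`, `q`, `variable`, `method`) with attributes `fdr` and
#'   `n_nonconverged`.
#' @export
test_variability <- function(normM, samples,
                             weights = NULL,
                             method = c("lmm_lrt", "lm_anova", "kruskal"),
                             fdr = 0.10, boundary_mixture = FALSE) {
  method <- match.arg(method)
  m <- as_id_matrix(normM)
  samples <- samples[match(colnames(m), samples$sample_id), ]
  if (anyNA(samples$sample_id)) {
    stop("test_variability: matrix columns missing from sample sheet",
         call. = FALSE)
  }
  tab <- table(samples$cell_type)
  if (any(tab < 2)) {
    stop("test_variability: every cell type needs >= 2 samples",
         call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- matrix(1, nrow(m), ncol(m))
  }
  cell <- factor(samples$cell_type)
  y_all <- log(m + 1)
  n <- nrow(m)
  p <- rep(NA_real_, n)
  stat <- rep(NA_real_, n)

  if (method == "kruskal") {
    for (i in seq_len(n)) {
      kt <- tryCatch(stats::kruskal.test(m[i, ], cell), error = function(e) NULL)
      if (!is.null(kt)) { p[i] <- kt$p.value; stat[i] <- unname(kt$statistic) }
    }
  } else if (method == "lm_anova") {
    for (i in seq_len(n)) {
      fit <- tryCatch(
        stats::lm(y_all[i, ] ~ cell, weights = weights[i, ]),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        a <- stats::anova(fit)
        p[i] <- a[["Pr(>F)"]][1]
        stat[i] <- a[["F value"]][1]
      }
    }
  } else {
    for (i in seq_len(n)) {
      res <- tryCatch({
        df <- data.frame(y = y_all[i, ], cell = cell, w = weights[i, ])
        full <- suppressWarnings(suppressMessages(
          lme4::lmer(y ~ 1 + (1 | cell), data = df, weights = w,
                     REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular =
                       "ignore", calc.derivs = FALSE))
        ))
        null <- stats::lm(y ~ 1, data = df, weights = w)
        lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                             as.numeric(stats::logLik(null))))
        pv <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
        if (boundary_mixture) pv <- 0.5 * pv + 0.5 * (lrt <= 0)
        list(stat = lrt, p = min(1, pv))
      }, error = function(e) NULL)
      if (!is.null(res)) { p[i] <- res$p; stat[i] <- res$stat }
    }
  }

  q <- rep(NA_real_, n)
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], "BH")
  out <- tibble::tibble(
    loop_id = rownames(m), statistic = stat, p = p, q = q,
    variable = !is.na(q) & q < fdr, method = method
  )
  attr(out, "fdr") <- fdr
  attr(out, "n_nonconverged") <- sum(!ok)
  class(out) <- c("loop_variability", class(out))
  out
}

#' @export
tidy.loop_variability <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.loop_variability <- function(x, ...) {
  tibble::tibble(
    n_tested = sum(!is.na(x$p)),
    n_variable = sum(x$variable),
    fdr = attr(x, "fdr"),
    method = x$method[1],
    n_nonconverged = attr(x, "n_nonconverged")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
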