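#' Fisher's exact test for a 2x2 table
#'
#' Full hypergeometric enumeration over all tables with the observed margins;
#' the two-sided p-value is the sum of probabilities of tables no more
#' probable than the observed one (with 1e-7 relative slack on the
#' comparison to absorb float noise). A zero margin gives p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  .assert(all(dim(tab) == 2) && all(tab >= 0) && all(tab == round(tab)),
          "need a 2x2 table of nonnegative integers")
  r <- rowSums(tab); s <- colSums(tab); N <- sum(tab)
  if (any(r == 0) || any(s == 0)) return(1)
  lo <- max(0, r[1] - s[2]); hi <- min(r[1], s[1])
  xs <- lo:hi
  probs <- stats::dhyper(xs, s[1], s[2], r[1])
  p_obs <- stats::dhyper(tab[1, 1], s[1], s[2], r[1])
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Freeman-Halton exact test for an r x c table
#'
#' Generalizes Fisher's exact test: complete enumeration of all tables with
#' the observed margins under the multivariate hypergeometric null,
#' `p = sum` of probabilities of tables no more probable than observed
#' (1e-7 relative slack). Intended for the small contingency tables of a
#' baseline-characteristics table.
#'
#' @param tab r x c matrix of nonnegative integer counts (total <= 1e4).
#' @param budget maximum number of tables to enumerate.
#' @return Two-sided p-value.
#' @export
fisher_exact_rxc <- function(tab, budget = 2e6) {
  tab <- as.matrix(tab)
  .assert(all(tab >= 0) && all(tab == round(tab)), "counts must be nonnegative integers")
  .assert(sum(tab) <= 1e4, "table total too large")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  rows <- rowSums(tab); cols <- colSums(tab); N <- sum(tab)
  # log-probability of a table with fixed margins
  log_const <- sum(lfactorial(rows)) + sum(lfactorial(cols)) - lfactorial(N)
  logp <- function(m) log_const - sum(lfactorial(m))
  lp_obs <- logp(tab)
  total <- 0
  counter <- 0
  nr <- nrow(tab); nc <- ncol(tab)
  rec <- function(ri, cols_left, acc_lp) {
    if (ri == nr) {
      if (any(cols_left < 0)) return()
      counter <<- counter + 1
      .assert(counter <= budget,
              "enumeration budget exceeded for exact r x c test")
      lp <- acc_lp - sum(lfactorial(cols_left))
      if (lp <= lp_obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    fill <- function(ci, rem_row, cl, lp_acc) {
      if (ci == nc) {
        if (rem_row <= cl[nc]) {
          cl2 <- cl; cl2[nc] <- cl2[nc] - rem_row
          rec(ri + 1, cl2, lp_acc - lfactorial(rem_row))
        }
        return()
      }
      for (v in 0:min(rem_row, cl[ci])) {
        cl2 <- cl; cl2[ci] <- cl2[ci] - v
        fill(ci + 1, rem_row - v, cl2, lp_acc - lfactorial(v))
      }
    }
    fill(1, rows[ri], cols_left, acc_lp)
  }
  rec(1, cols, log_const)
  min(1, total)
}

.bin_age <- function(age) factor(ifelse(age <= 55, "<=55", ">55"),
                                 levels = c("<=55", ">55"))

#' Baseline-characteristics table with per-variable tests
#'
#' Produces the counts/percentages per response group for each categorical
#' variable with two p-values per row: Fisher's exact test (enumeration) and
#' the continuity-corrected chi-square test (plain Pearson for > 2 levels).
#' Tumor size, being continuous, is summarised as mean (SD) with Student and
#' Welch t-test p-values.
#'
#' @param cohort data frame with `response` and any of `sex`, `site`, `age`,
#'   `cea`, `afp`, `tumor_size`.
#' @return Data frame: `variable`, `level`, `NOR`, `OR`, `p_fisher`,
#'   `p_chisq` (for tumor size: `p_fisher` = Welch, `p_chisq` = Student,
#'   labelled in `variable`).
#' @export
table2_report <- function(cohort) {
  .assert("response" %in% names(cohort), "cohort needs a response column")
  resp <- factor(cohort$response, levels = c("NOR", "OR"))
  .assert(all(table(resp) > 0), "empty response group")
  vars <- list()
  if ("sex" %in% names(cohort)) vars$sex <- factor(cohort$sex)
  if ("site" %in% names(cohort)) vars$site <- factor(cohort$site)
  if ("cea" %in% names(cohort)) vars$cea <- factor(cohort$cea)
  if ("afp" %in% names(cohort)) vars$afp <- factor(cohort$afp)
  if ("age" %in% names(cohort)) vars$age <- .bin_age(cohort$age)
  out <- list()
  for (v in names(vars)) {
    tab <- table(vars[[v]], resp)
    if (nrow(tab) < 2) {
      out[[v]] <- data.frame(variable = v, level = rownames(tab)[1],
                             NOR = tab[1, "NOR"], OR = tab[1, "OR"],
                             p_fisher = 1, p_chisq = 1)
      next
    }
    pf <- if (nrow(tab) == 2) fisher_exact_2x2(tab) else fisher_exact_rxc(tab)
    pc <- suppressWarnings(chisq.test(tab)$p.value)
    out[[v]] <- data.frame(variable = v, level = rownames(tab),
                           NOR = as.numeric(tab[, "NOR"]),
                           OR = as.numeric(tab[, "OR"]),
                           p_fisher = c(pf, rep(NA, nrow(tab) - 1)),
                           p_chisq = c(pc, rep(NA, nrow(tab) - 1)))
  }
  if ("tumor_size" %in% names(cohort)) {
    sz <- cohort$tumor_size
    ms <- tapply(sz, resp, function(z) sprintf("%.2f (%.2f)", mean(z), sd(z)))
    p_w <- stats::t.test(sz ~ resp)$p.value
    p_s <- stats::t.test(sz ~ resp, var.equal = TRUE)$p.value
    out$tumor_size <- data.frame(variable = "tumor_size (mean (SD); Welch/Student t)",
                                 level = "cm", NOR = NA, OR = NA,
                                 p_fisher = p_w, p_chisq = p_s)
    out$tumor_size$NOR <- ms["NOR"]; out$tumor_size$OR <- ms["OR"]
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
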