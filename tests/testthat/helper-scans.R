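# fixture builders shared across test files

mk_scan <- function(g, spacing = c(5, 10), eye = "e1", stage = "pre",
                    axis = "horizontal") {
  storage.mode(g) <- "integer"
  labeled_bscan(g, spacing, eye, stage, axis)
}

# axis-aligned rectangular hole
rect_hole <- function(rows = 30, cols = 40, r = 5:24, co = 11:20,
                      spacing = c(5, 10), ...) {
  g <- matrix(0L, rows, cols)
  g[r, co] <- 1L
  mk_scan(g, spacing, ...)
}

# trapezoidal hole: base width at bottom row, narrowing linearly upward
trapezoid_hole <- function(base_w = 20, top_w = 10, n_rows = 11,
                           rows = 40, cols = 60, r_base = 30,
                           spacing = c(5, 10), ...) {
  g <- matrix(0L, rows, cols)
  cc <- cols %/% 2
  for (i in 0:(n_rows - 1)) {
    w <- round(base_w + (top_w - base_w) * i / (n_rows - 1))
    left <- cc - w %/% 2
    g[r_base - i, left:(left + w - 1)] <- 1L
  }
  mk_scan(g, spacing, ...)
}

# horizontal band (one row) with optional column gaps removed
band_scan <- function(code, span = 1:100, gaps = NULL, rows = 10,
                      cols = 120, row = 5, spacing = c(5, 10), ...) {
  g <- matrix(0L, rows, cols)
  g[row, span] <- code
  if (!is.null(gaps)) g[row, gaps] <- 0L
  mk_scan(g, spacing, ...)
}

# small deterministic clinical table
toy_clinical <- function() {
  data.frame(
    eye_id = c("a", "b"), age = c(66, 71), sex = c("F", "M"),
    duration_days = c(30, 120), etdrs_pre = c(50, 40),
    etdrs_wk2 = c(70, 45), etdrs_mo3 = c(69, NA), etdrs_mo6 = c(75, 61),
    etdrs_mo12 = c(80, 62), stringsAsFactors = FALSE
  )
}

# brute-force all-pairs AUC oracle (independent of the rank formulation)
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct likelihood maximiser, the independent logistic oracle
logistic_optim <- function(x, y) {
  X <- cbind(1, as.matrix(x))
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}
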