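# Thin wrapper around libsvm (e1071) for linear maximum-margin classification.
# Training columns are mean-centered with training statistics by the callers;
# here we only extract the primal hyperplane so decision values and geometric
# distances can be computed explicitly.

# Fit a linear soft-margin SVM (C = 1 by default). `y` must be a 2-level
# factor. Returns the hyperplane (w, b) with decision f(x) = x.w + b, positive
# side = `positive_class`.
fit_linear_svm <- function(x, y, cost = 1) {
  stopifnot(is.factor(y), nlevels(y) == 2)
  m <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  list(w = w, b = -m$rho, w_norm = sqrt(sum(w^2)),
       positive_class = m$levels[m$labels[1]])
}

# Decision values f(x) = x.w + b for rows of `x`.
svm_decision <- function(fit, x) {
  drop(x %*% fit$w) + fit$b
}

# Predicted labels; ties at the boundary (f == 0) get NA so they count as
# errors under the conservative tie rule.
svm_predict <- function(fit, x, levels2) {
  f <- svm_decision(fit, x)
  neg <- setdiff(levels2, fit$positive_class)
  out <- ifelse(f > 0, fit$positive_class, ifelse(f < 0, neg, NA_character_))
  out
}
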