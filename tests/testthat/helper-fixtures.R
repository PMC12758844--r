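# Small fixtures built in code for the unit tests.

# Tiny MEG-like config: 6 sources per region keeps generation fast while all
# structural invariants (cells, splits) still hold.
tiny_meg_config <- function(..., seed = 1L) {
  args <- list(n_trials_per_condition = 16,
               regions = c(evc = 6, otc = 6, ppc = 6), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(meg_sim_config, args)
}

tiny_fmri_config <- function(..., seed = 1L) {
  args <- list(n_subjects = 1, rois = c(foveal_v1 = 150), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(fmri_sim_config, args)
}

# Separable 2-D toy set with a known maximum-margin hyperplane: 4 points per
# class at x1 = +/-1 (x2 symmetric), for which the C=1 soft-margin solution
# is w = (1, 0), b = 0, so the geometric distance of any point equals its x1
# coordinate.
toy_margin_set <- function() {
  x <- rbind(c(1, 0.5), c(1, -0.5), c(1, 1.5), c(1, -1.5),
             c(-1, 0.5), c(-1, -0.5), c(-1, 1.5), c(-1, -1.5))
  y <- factor(rep(c("p", "n"), each = 4), levels = c("n", "p"))
  list(x = x, y = y)
}
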