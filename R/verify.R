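#' Run the built-in desk-verification checks
#'
#' Recomputes every desk-verifiable quantity of the architecture from scratch
#' and compares it with the published value: the six pinned layer-table
#' parameter counts, the analytic and instrumented computation ratio of the
#' ghost-inception convolution, the F1 recomputation from published
#' precision/recall, and the relative GFLOPs reduction.
#'
#' @param seed RNG seed used for all constructions.
#' @return data.frame with columns `check`, `computed`, `expected`, `pass`.
#' @export
verify <- function(seed = 1L) {
  rows <- list()
  add <- function(check, computed, expected) {
    rows[[length(rows) + 1L]] <<- data.frame(check = check, computed = computed,
                                             expected = expected,
                                             pass = isTRUE(all.equal(computed, expected)),
                                             stringsAsFactors = FALSE)
  }
  add("stem Conv parameters",
      param_count(with_seed(seed, nn_conv(3L, 32L, 3L, 2L))), 928)
  stages <- list(c(32, 64, 11296), c(128, 128, 81728),
                 c(256, 256, 326272), c(256, 512, 713984))
  for (s in stages) {
    add(sprintf("GIConv %d->%d parameters", s[1], s[2]),
        param_count(with_seed(seed, nn_giconv(giconv_config(s[1], s[2])))), s[3])
  }
  add("SPPF parameters",
      param_count(with_seed(seed, nn_sppf(512L, 512L))), 656896)
  add("analytic ratio S at k=3, n=2c (1 d.p.)", round(cost_ratio(3, 128, 64), 1), 0.6)
  cfg <- giconv_config(64L, 128L, 3L, 2L)
  gi <- with_seed(seed, nn_giconv(cfg))
  x <- array(0.1, c(40, 40, 1, 64))
  macs <- count_macs(function() gi$forward(tn_leaf(x)))
  add("instrumented GIConv MACs / standard conv (%)",
      round(100 * macs / giconv_cost(cfg, 20, 20)$macs_standard), 60)
  add("F1 from published P/R pair (1 d.p.)", round(f1_score(84.7, 82.2), 1), 83.4)
  add("relative GFLOPs reduction (%)", round(cost_reduction_percent(21.6, 18.7), 1), 13.4)
  do.call(rbind, rows)
}
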