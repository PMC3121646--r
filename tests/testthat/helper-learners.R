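# Auxiliary learners registered for protocol tests: the exact Bayes
# posterior of a known mixture (a perfectly calibrated classifier that
# ignores the training sample) and a pure-noise classifier.

register_learner("bayes_oracle", function(x, y, newx, params) {
  bayes_posterior(params$cfg, newx)
})

register_learner("noise", function(x, y, newx, params) {
  g <- matrix(rexp(nrow(newx) * nlevels(y)), nrow(newx))
  colnames(g) <- levels(y)
  g / rowSums(g)
})
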