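Package: noveltyGain
Title: Bayesian Information-Gain Model of Novelty-Elicited Emotion
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a Bayesian model of the emotions elicited by novel
    events. Emotional arousal is quantified as information gain, the
    Kullback-Leibler divergence of a conjugate Gaussian posterior from its
    prior, and decomposed into prediction error, prior uncertainty, and
    sensory noise. The decomposition yields the arousal crossover effect:
    higher uncertainty raises arousal at small prediction errors but lowers
    it at large ones. Hedonic valence is modelled as the sum of reward and
    aversion sigmoids of information gain, giving an inverted-U (Wundt)
    curve. The package also ships a synthetic replica of a 2x2
    within-subject audiovisual-incongruity experiment (trial schedules,
    Likert surprise ratings, event-related-potential epochs with P300
    extraction) and a repeated-measures ANOVA engine, so the model's
    predictions can be demonstrated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
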