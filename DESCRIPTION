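Package: limbloop
Title: Closed-Loop MIMO Neuromusculoskeletal Model of the Human Upper Limb
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Linear time-invariant multiple-input multiple-output model of
    the human upper limb (15 plant muscles, 7 joint degrees of freedom)
    with short-loop afferent feedback: proportional-derivative muscle
    spindle feedback and homonymous Golgi tendon organ force feedback with
    Pade-approximated neural transmission delays. Provides the estimation
    pipeline that compiles relative spindle gains from heterogeneous
    reflex measurements (post-stimulus time histograms and EMG averaging),
    force-feedback gains inversely proportional to maximum muscle force,
    least-squares decomposition of round-trip reflex delays into afferent
    and efferent components, stability-based scaling of relative to
    absolute gains via the system-wide multiloop gain margin, and step,
    frequency and pole analyses of the interconnected system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
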