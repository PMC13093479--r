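Package: qimpath
Title: Tunneling Splittings from the Imaginary-Mode Reaction Path
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes vibrational tunneling splittings of double-well
    systems (hydrogen transfer and related large-amplitude motions) from a
    reduced-dimensionality reaction path along the imaginary-frequency
    normal mode of the transition state. Provides normal-mode analysis with
    translation/rotation projection, constrained-Newton relaxation of the
    potential along the path, a sinc discrete variable representation (DVR)
    solver in one and two dimensions, harmonic extension of the repulsive
    walls, projection of intrinsic-reaction-coordinate data onto the path,
    and a two-level analysis of asymmetric double wells, together with
    analytic model potentials with closed-form relaxed paths for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, optparse
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
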