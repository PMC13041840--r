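Package: pboldqa
Title: Quality Assurance for Multi-Echo fMRI via TE-Dependence of Covariance Connectivity
Version: 0.1.0
Authors@R:
    person("pboldqa", "developers", email = "pboldqa@example.org", role = c("aut", "cre"))
Description: Computes p_BOLD, a scan-level quality-assurance metric for
    multi-echo fMRI that quantifies whether inter-regional covariance
    connectivity scales with echo time (as BOLD/T2* fluctuations must) or is
    echo-time independent (as net-magnetization/S_o artifacts are). Includes
    companion QA metrics (temporal signal-to-noise ratio, background
    thermal-noise estimation), a multi-echo signal simulator built on the
    mono-exponential T2* decay model for self-contained validation, minimal
    NIfTI-1 input/output, ROI extraction against labeled atlases or sphere
    tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
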