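Package: tusmod
Title: Transcranial Ultrasound Dosimetry and Connectional Fingerprint Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline transcranial focused ultrasound (TUS) study tooling:
    maps CT-like Hounsfield-unit head volumes to acoustic media via a
    porosity attenuation model, estimates focused pressure fields with a
    Rayleigh surface integral, computes pulse intensity metrics, and solves
    the Pennes bioheat equation with an explicit finite-difference scheme to
    bound thermal dose. Also implements a resting-state fMRI analysis stack:
    compartment-PCA confound regression with Volterra-expanded motion terms,
    temporal filtering with dynamically detected band-stop notches, seed-based
    bounded Fisher-z coupling maps, connectional fingerprints, and a
    cosine-similarity permutation test with exhaustive relabelling. A
    synthetic-data module generates head phantoms and multi-run BOLD datasets
    with planted network coupling, a connectivity sharpening effect, and a
    meningeal global confound, so the full pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
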