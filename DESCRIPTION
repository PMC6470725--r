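Package: pepdyn
Title: Conformational Ensemble Analysis for Disulfide-Rich Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for peptide conformational
    ensembles, built around the analyses used to compare chlorotoxin-like
    disulfide-substitution analogs: DSSP-style secondary-structure
    assignment with Kabsch-Sander hydrogen-bond energies, least-squares
    superposition (RMSD, iterative mean structures, RMSF), residue contact
    probability maps and geometric hydrogen bonds, the CbetaHbeta
    center-of-mass contact statistic with its one-sided 95% confidence
    threshold, Shrake-Rupley solvent-accessible surface area with rSASA
    normalisation and hydration-shell water probabilities, dihedral
    principal component analysis with free-energy landscapes and k-means
    basin extraction, and RMSIP/nRMSIP essential-subspace overlap.
    Includes generators for synthetic ensembles with known ground truth
    (Markov-switching von Mises dihedrals, prescribed-covariance Cartesian
    fluctuations, controlled-density solvation scenes) so every analysis
    stage can be validated without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, bio3d, cluster, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry-utils.R'
    'core-io.R'
    'selections.R'
    'synthetic-dihedrals.R'
    'synthetic-cartesian.R'
    'synthetic-solvation.R'
    'superposition.R'
    'secondary-structure.R'
    'contacts.R'
    'solvation.R'
    'dpca.R'
    'fel.R'
    'essential-subspace.R'
    'pipeline.R'
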