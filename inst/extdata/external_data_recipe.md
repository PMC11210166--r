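# Recipe: reproducing the full exposure-to-prostate-cancer analysis

The packaged fixtures carry only the exposure-side instruments (the BPH and
prostatitis association tables). The outcome-side statistics — each
instrument's association with malignant neoplasm of prostate in the
MRC-IEU 2018 UK Biobank GWAS (463 010 European participants) — were taken
from the IEU Open GWAS project (https://gwas.mrcieu.ac.uk/), whose accession
identifiers are not recorded in the packaged metadata. Reproducing the
headline causal estimates therefore requires a one-time download:

1. On the IEU Open GWAS index, locate the MRC-IEU 2018 UK Biobank dataset
   for "Malignant neoplasm of prostate" (N = 463 010, European). Candidate
   accessions match the `ukb-b-*` series; confirm the phenotype label and N
   against `load_fixture("study_meta")`.
2. Extract the 33 instrument rsIDs (`load_fixture("bph_instruments")`,
   `load_fixture("prostatitis_instruments")`) from that dataset and export
   them as a TSV with columns SNP/EA/NEA/EAF/BETA/SE/P.
3. Run the pipeline with the packaged exposure fixture and your outcome
   file:

       mrpipe run --config analysis.yaml

   where `analysis.yaml` sets `exposure: fixture:bph_instruments`,
   `outcome: /path/to/pca_outcome.tsv`, and `model: auto_by_q`.

With the true outcome data the pipeline reproduces the reported analysis:
IVW (random-effects, chosen because Cochran's Q p < 0.05), MR-Egger and its
intercept test, MR-PRESSO (global / outlier / distortion) and leave-one-out.
No test in this package depends on this download.
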