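# Reference fixtures

Transcriptions of the published reference tables from the oral-leukoplakia
malignant-transformation module study that this package's pipeline models.
They are data files, not code, so the transcription stays auditable and
diff-able; `reference_checksums.tsv` carries MD5 checksums that
`reproduce_reference_tables()` verifies before recomputing anything.

- `reference_modules.tsv` — the 13 modules associated with oral cancer
  (MAOCs) in long format; `is_deg = 1` marks members reported as
  differentially expressed (typeset in bold in the source table).
- `reference_oral_cancer_genes.tsv` — the 30 module genes annotated as
  oral-cancer related, with their GeneCards relevance scores.
- `reference_topology.tsv` — hub genes with degrees, and intra-/inter-MAOC
  connector genes with connecting scores. Degrees are only published for
  the hub genes and (in the accompanying narrative) for RAF1 (degree 10);
  unpublished degrees are NA. RAF1's degree is included so the
  hub-threshold recomputation has a published non-hub gene.
- `reference_regulators.tsv` — the 8 miRNA regulators of modules with
  expression-change directions for the miRNA and each target gene
  (one row per miRNA-target pair). Directions are transcribed verbatim,
  including case. Known transcription caveat: the source narrative
  describes hsa-miR-491-3p as down-regulated while its table prints "Up";
  this fixture encodes the table and does not resolve the discrepancy.
- `reference_summary.tsv` — the published summary figures these fixtures
  should reproduce (unique module gene count, DEG percentage, overlap with
  the annotated oral-cancer list, anti-correlated miRNA count, hub calls).
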