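# ihcscore

Prioritization of cancer marker candidates from ordinal immunohistochemistry
(IHC) staining annotations.

Antibody-based tissue atlases annotate each IHC staining result with two
ordinal labels: *Intensity* (Negative/Weak/Moderate/Strong) and *Quantity*
(fraction of positively stained cells: Negative/Rare/<25%/25–75%/>75%).
Screening a proteomics candidate list against such a resource by eye is slow
and subjective. `ihcscore` quantifies the annotations and ranks antibodies
per cancer-to-normal tissue *mapping* (27 mappings covering 20 cancer types
in the packaged registry), for researchers filtering marker candidates ahead
of wet-lab validation.

## The method

Labels map to numbers, I ∈ {3,2,1,0} and Q ∈ {75,50,25,5,0}, and I×Q ∈
[0, 225] is the expression level of one staining result. For antibody *a*
and mapping *m*:

- **EiN** = I×Q of the single normal-cell-type annotation;
- **EiC** = mean I×Q over the ≤ 12 patient samples of the mapping's cancer
  type;
- **ED** = EiC − EiN, the overexpression signal;
- **SG** (significance) = Φ((ED − μ_g)/σ_g), z-scored over all antibodies of
  the mapping — the antibody's rank among antibodies;
- **SP** (specificity) = Φ((ED − μ_p)/σ_p), z-scored over all mappings of
  the antibody — the mapping's rank among the antibody's mappings;
- **score** = EiC · SG · SP ∈ [0, 225], high only for proteins abundant in
  the cancer whose overexpression is significant *and* cancer-specific.

Downstream tooling: top-k validation by one-sample t-tests of EiC/ED means,
an ED heat-map matrix (selection mapping × evaluation mapping), candidate
filtering rules (score ≥ 100 in a target mapping; mean fold change ≥ 2;
fold change ≥ 2 in more than 14 patients) with the eight on/off rule
combinations, and a seeded synthetic annotation/cohort generator with
planted ground truth. See `vignettes/scoring-method.Rmd` for the model,
parameter defaults and design rationale.

## Worked example

The packaged fixture holds the staining records of antibody HPA034966 on
breast tissue: one normal glandular-cell annotation (Moderate, >75%) and
twelve breast-cancer patient annotations (three Strong >75%, nine
Moderate >75%).

```r
library(ihcscore)
ann  <- readAnnotations(exampleAnnotationFile())
sset <- buildEDMatrix(ann, loadMappingRegistry())
c(EiN = eiN(sset)["HPA034966", "Breast"],
  EiC = eiC(sset)["HPA034966", "Breast"],
  ED  = edMatrix(sset)["HPA034966", "Breast"])
#>    EiN    EiC     ED
#> 150.00 168.75  18.75
```

EiN = 2×75 = 150; EiC = 2025/12 = 168.75; the protein is mildly
overexpressed (ED = 18.75) in breast cancer relative to normal glandular
cells.

On synthetic data with one planted mapping-specific marker per mapping
(latent effect 3 SD), the planted breast-mapping antibody `AB0001` ranks
first with SG and SP near 1:

```r
sim <- simulateAnnotations(simConfig(nAntibodies = 60,
    plantedMarkers = plantMarkers(60, perMapping = 1, effect = 3), seed = 1))
scored <- scoreAntibodies(sim$annotations, loadMappingRegistry())
tab <- scoresTable(scored)
head(tab[tab$mapping_id == "Breast", ], 3)
#>   antibody_id  gene mapping_id EiN    EiC n_patients     ED     SG     SP  score rank
#> 1      AB0001 G0001     Breast   0 225.00         12 225.00 0.9945 0.9876 221.00    1
#> 2      AB0017 G0017     Breast   0  98.75         12  98.75 0.8881 0.8593  75.36    2
#> 3      AB0046 G0046     Breast   0  83.75         12  83.75 0.8551 0.8700  62.31    3
```

Top-k validation shows the published pattern — top-ranked antibodies have
strongly positive mean ED while the population trend is negative:

```r
v <- validateTopkMeans(scored, k = 10)
head(v[v$statistic == "ED", ], 3)
#>   mapping_id statistic population_mean n_top sample_mean sample_sd     t   p_value
#> 2     Breast        ED          -16.81    10       90.88     48.53 7.017 3.103e-05
#> 4  Carcinoid        ED          -16.92    10       90.88     51.27 6.648 4.695e-05
#> 6 Cervical-A        ED          -26.17    10       81.50     53.95 6.311 6.960e-05
```

Applying all three filtering rules (combination 8) to the packaged
synthetic reconstruction of the colorectal-cancer case study keeps the four
published candidates, ANXA4 surviving on exactly 15 qualifying patients:

```r
rep8 <- applyCombination(8, readCohort(exampleCohortFile(), quiet = TRUE),
                         readScores(exampleScoresFile()),
                         readGeneAnnotations(exampleGeneAnnotationFile()))
candidateTable(rep8)
#>      gene best_score mean_fold_change n_qualifying_patients is_biomarker is_disease_related
#> 3 CEACAM5      200.5             6.41                    24         TRUE               TRUE
#> 4 CEACAM6      155.2             4.32                    21         TRUE               TRUE
#> 1   ANXA4      138.8             2.07                    15        FALSE               TRUE
#> 2    CAMP      132.9             4.29                    20         TRUE               TRUE
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's reference quantities from scratch through the
installed package — the worked-example expression level in normal breast
glandular cells, and the maximum expression level attainable under the
ordinal transforms (maximized over all 4×5 label combinations) — and writes
them as JSON.
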