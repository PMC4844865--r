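# appendixsom

Fully automatic extraction and millimetre measurement of the vermiform
appendix from B-mode abdominal ultrasound frames, for researchers building
computer-aided appendicitis screening tools. An outer appendix diameter of
6 mm or more under compression is the most accurate sonographic criterion
for acute appendicitis, so the package's end product is a segmented appendix
with its minor-axis diameter in millimetres and a 6 mm flag.

## Method

The pipeline exploits the anatomy of the right lower quadrant: the appendix
lies in the organ area **below the bottom fascia line**, a bright
(hyperechoic), horizontally elongated band in the abdominal wall.

1. **Crop** the scan region (header/ruler margins).
2. **Ends-in search stretching**: intensities between the low and high
   histogram quantiles (defaults 5 %/95 %) are mapped linearly onto 0–255.
3. **Trapezoidal fuzzy binarization**: with `I_Min`, `I_Max` the ROI
   extremes and `T = (I_Min + I_Max)/2`, the membership plateau is
   `[I_s, I_e]` with `I_s = T/3`, `I_e = 2 I_s`; a pixel is foreground iff
   its membership reaches the α-cut (0.5). The falling shoulder is the
   decreasing mirror of the rising one, so `μ(I_Max) = 0`.
4. **Fascia detection**: 8-directional (Moore) contour tracking and
   connected-component analysis; objects wider than one third of the ROI
   width and with elongation ≥ 4 are fascia segments. Disconnected segments
   are reconnected with a **cubic spline** through their lower boundaries,
   and everything at or above the bottom fascia line is removed from the
   search region.
5. **SOM quantization**: a 4×4 **hexagonal-grid self-organizing map** with
   scalar intensity weights is trained online (Gaussian neighbourhood,
   exponentially decaying learning rate and radius) on the sub-fascial
   pixels; each pixel is replaced by its best-matching unit's weight,
   posterizing the region into at most 16 levels.
6. **Appendix extraction**: the darkest quantized levels (the hypoechoic
   lumen) form the candidate mask; candidates are filtered by physical size
   and solidity, the best candidate is hole-filled and re-traced, and the
   **second-moment ellipse** gives diameter (minor axis) and length (major
   axis) in millimetres, plus the shape-brightness pattern label (A–D).

Because clinical images cannot ship with the package, a seeded **phantom
generator** emulates the four clinically observed shape-brightness patterns
(A: oval in brighter surroundings; B: hooked; C: strongly hypoechoic oval;
D: long low-contrast oval) over a speckled fascia/wall anatomy, with
ground-truth masks, so every stage and the full pipeline are testable.

## Worked example

```r
library(appendixsom)

ph  <- generate_phantom(default_phantom_spec("C", seed = 1))
res <- run_pipeline(ph$image, pipeline_config(seed = 1))
res
#> <appendix_result> diameter 9.04 mm, length 13.04 mm, MEETS 6 mm criterion, pattern C
dice(res$mask, ph$truth$appendix_mask)
#> [1] 0.9964749
```

The type-C phantom was built with a 9 mm × 13 mm appendix; the pipeline
recovers a 9.04 mm diameter (0.4 % error), flags it as meeting the 6 mm
appendicitis criterion, classifies the oval/high-contrast pattern as C, and
overlaps the ground truth with Dice 0.996.

Batch evaluation over 15 phantoms per pattern type:

```r
evaluate_phantoms(seeds = 1:15, cfg = pipeline_config())
#> Phantom-batch appendix extraction report
#>     type  n extracted extraction_rate mean_dice
#>        A 15        15          100.0%     0.988
#>        B 15        15          100.0%     0.999
#>        C 15        15          100.0%     0.992
#>        D 15        11           73.3%     0.605
#>  overall 60        56           93.3%     0.896
```

Types C and A are the easiest, the long low-contrast type D the hardest —
the difficulty ordering clinicians report for these patterns.

## Command line

```sh
inst/cli/appendixsom phantom --type C --n 15 --seed 1 --out phantoms/
inst/cli/appendixsom run phantoms/C_001_image.png --spacing 0.1 --out out/
inst/cli/appendixsom evaluate phantoms/ --out out/
```

`run` accepts DICOM (embedded pixel spacing is used) or 8-bit PNG/TIFF with
`--spacing`; it writes `result.json` plus mask and overlay PNGs.

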