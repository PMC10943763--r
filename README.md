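# flycourt

Automated recognition of male *Drosophila* courtship from backlit arena
video, for behavioral labs that score courtship elements — not just
locomotion — across many pairs at once.

A male fly courts in stereotyped elements: **orientation** (facing the
female), **tapping** (touching her abdomen with a foreleg), **singing**
(wing extension and vibration), **attempted copulation** (bending the
abdomen and mounting), and **copulation**. flycourt turns raw frames of one
male/female pair in an 11-mm circular arena into a per-frame ethogram of
these elements and the summary statistics built on it, using pure image
processing — no training data, and only the behavioral definitions to
retune when the rig changes.

The pipeline, per arena:

1. **Arenas** — circle Hough transform plus algebraic rim refinement on the
   first frame; the 11-mm diameter calibrates px → mm.
2. **Silhouettes** — background from a spatial maximum filter (flies are
   dark on a backlight), then thresholded background subtraction.
3. **Wings vs torso** — wing pixels satisfy `round((R/80)(G/80)(B/80)) > 0`
   (translucent wings are brighter than the opaque torso); torso =
   silhouette minus wings, with morphological cleanup.
4. **Pose** — the torso's moment-equivalent ellipse gives position, the
   head/tail candidates (axis endpoints; the head is farther from the
   whole-body centroid, because wings trail), heading, eccentricity
   `sqrt(1 - (minor/major)^2)`, and per-side wing-extension angles θ, θ′
   measured from the tailward axis to the wingtips.
5. **Identity** — constant-velocity prediction frame to frame; spectral
   clustering splits merged silhouettes during overlap; and after every
   overlap the identities are verified by torso shape matching: watershed
   the torso's distance map into head/thorax/abdomen, compare each part to
   stored references by centroid-aligned Dice coefficients, and accept a
   pairing when max + min of the three values exceeds 1.6. Wrong
   assignments after a crossing are detected and corrected instead of
   persisting.
6. **Behavior** — per-frame detectors (singing > 30°; orientation within a
   2.5×, ±10° sector; tapping via a six-step leg-contact cascade including
   the leg-seen-through-wing case; attempted copulation when eccentricity
   drops below 0.9× a straight male's with the head within 1 mm of the
   female's tail), a >5-of-12-frame certification filter with priority
   copulation > attempted copulation > tapping > singing > orientation, and
   promotion of any half-minute attempted-copulation run to copulation.
7. **Analytics** — total courtship time, element proportions, and the
   row-normalized behavioral transition matrix, with tidy/glance/autoplot
   methods.

A parametric scene renderer (`fly_spec()`, `scene_spec()`,
`render_frame()`, scripted sequences) draws synthetic pairs with exact
ground truth, so the whole pipeline is testable without recorded video.

## Worked example

Score a scripted courtship bout (the same kind of sequence the test suite
validates against):

```r
library(flycourt)

bout <- script_courtship_bout()                 # scenes + ground truth, 2 fps
rc   <- render_cropped_sequence(bout$scenes[1:150], seed = 42, fps = bout$fps)
cfg  <- flycourt_config(fps = bout$fps, arena = list(precropped = TRUE),
                        identity = list(male_hint = c(195, 75)))
res  <- run_pipeline(rc$crops, cfg)

glance(res[[1]]$ethogram)
#>   n_frames fps window_frames total_courtship_s courtship_index copulated
#> 1      150   2           150                49       0.6533333     FALSE

res[[1]]$proportions
#>                element frames proportion
#> 1          orientation     21  0.1400000
#> 2              tapping     52  0.3466667
#> 3              singing     25  0.1666667
#> 4 attempted_copulation      0  0.0000000
#> 5           copulation      0  0.0000000
#> 6                 none     52  0.3466667
```

The male courted for 49 of 75 s (courtship index 0.65): he oriented, sang,
then tapped the female through two leg-contact bouts; attempted copulation
comes later in the full script and, once sustained past half a minute, is
promoted to copulation. The transition matrix for this slice shows a single
direct change, orientation → singing with probability 1 — the other element
switches in the script pass through quiescent stretches, which break
transition chains by default (`bridge_none = TRUE` bridges them):

```r
transition_matrix(res[[1]]$ethogram, include_copulation = FALSE)$probabilities
#>                       to
#> from                   orientation tapping singing attempted_copulation
#>   orientation                    0       0       1                    0
#>   tapping                       NA      NA      NA                   NA
#>   singing                       NA      NA      NA                   NA
#>   attempted_copulation          NA      NA      NA                   NA
```

`autoplot()` on the ethogram, the transition matrix, or
`courtship_pattern_summary()` draws the label timeline, the transition
heatmap, and the courtship-pattern diagram. `run_pipeline(source, cfg,
out_dir = ...)` accepts a directory of numbered PNG/TIFF frames and writes
per-arena CSVs, a summary JSON, and a run manifest;
`inst/cli/flycourt.R` wraps the same functions as `track`, `analyze`,
`render-fixtures`, and `annotate` commands.

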