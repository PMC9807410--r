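# Column dictionary for nutristock input tables

All inputs are UTF-8 CSV/TSV files with a header row; the delimiter is
inferred from the extension (`.tsv`/`.tab`/`.txt` tab, otherwise comma).

## demographics (one municipality per file)
| column | type | meaning |
|---|---|---|
| municipality | string | municipality name (identical in every row) |
| sex | `male` / `female` | stratum sex |
| age_group | string | stratum age-group label; must match the DRI table exactly |
| count | non-negative integer | resident head count of the stratum |

## dri (long format, complete nutrient x stratum grid)
| column | type | meaning |
|---|---|---|
| nutrient_id | string | short nutrient token (e.g. `energy`, `vit_b1`) |
| nutrient_name | string (optional) | display name |
| unit | string | measurement unit (kcal, g, mg, µg); constant per nutrient |
| sex | `male` / `female` | stratum sex |
| age_group | string | stratum age-group label |
| value | number >= 0 | reference amount per person per day, in `unit` |

The `shelter5` profile requires the ids `energy`, `protein`, `vit_b1`,
`vit_b2`, `vit_c`.

## catalog (one row per food)
Fixed columns: `id`, `name`, `category`, `shelf_stable`, `requires_cooking`,
`contains_wheat` (logicals), `pack_grams` (> 0, default 100),
`cost_per_pack`, `volume_per_pack` (litres; optional). Every other column
is a per-100 g nutrient composition column named by nutrient id.

## inventory
| column | type | meaning |
|---|---|---|
| food_id | string | catalog item id |
| quantity_grams | number >= 0 | stocked mass in grams |
| packs | number >= 0 | alternative to quantity_grams; converted via the catalog's `pack_grams` |

Exactly one of `quantity_grams` / `packs` is used. An empty file (header
only) is a valid empty inventory.
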