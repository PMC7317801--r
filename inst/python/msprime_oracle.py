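"""Independent structured-coalescent oracle based on msprime.

Reads a JSON config:
  {
    "n_demes": int,
    "adj": [[neighbour indices, 0-based], ...],
    "K": float,            # mean pairwise within-deme coalescence time (ky)
    "m": float,            # total per-lineage migration rate (1/ky)
    "samples_per_deme": int,
    "reps": int,
    "seed": int
  }

Simulates genealogies under msprime's structured coalescent with matched
rates (haploid population size K so the pair rate is 1/K; backwards
migration rate m/deg(u) from deme u to each neighbour) and prints JSON with
the per-deme-pair mean pairwise TMRCA (averaged over replicate means) and
the SD of the replicate means.
"""
import itertools
import json
import sys

import msprime
import numpy as np


def main(cfg_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    nd = cfg["n_demes"]
    adj = cfg["adj"]
    K = float(cfg["K"])
    m = float(cfg["m"])
    nper = int(cfg["samples_per_deme"])
    reps = int(cfg["reps"])
    seed = int(cfg["seed"])

    dem = msprime.Demography()
    for d in range(nd):
        dem.add_population(name=f"pop{d}", initial_size=K)
    for u in range(nd):
        deg = len(adj[u])
        for v in adj[u]:
            # backwards-time rate at which a lineage in u hops to v
            dem.set_migration_rate(source=f"pop{u}", dest=f"pop{v}",
                                   rate=m / deg)

    samples = {f"pop{d}": nper for d in range(nd)}
    pair_cats = list(itertools.combinations_with_replacement(range(nd), 2))
    acc = {c: [] for c in pair_cats}

    node_pop = {}
    for rep in range(reps):
        ts = msprime.sim_ancestry(samples=samples, demography=dem,
                                  ploidy=1, random_seed=seed + rep + 1)
        tree = ts.first()
        pops = ts.tables.nodes.population
        leaves = [u for u in ts.samples()]
        per_cat = {c: [] for c in pair_cats}
        for a, b in itertools.combinations(leaves, 2):
            pa, pb = int(pops[a]), int(pops[b])
            cat = (min(pa, pb), max(pa, pb))
            per_cat[cat].append(tree.tmrca(a, b))
        for c in pair_cats:
            if per_cat[c]:
                acc[c].append(float(np.mean(per_cat[c])))

    out = {}
    for (i, j), vals in acc.items():
        v = np.asarray(vals)
        out[f"{i}_{j}"] = {"mean": float(v.mean()),
                           "sd": float(v.std(ddof=1)),
                           "n": int(v.size)}
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main(sys.argv[1])
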