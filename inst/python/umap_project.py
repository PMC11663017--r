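"""2-D UMAP projection helper: reads a TSV matrix, writes 2-D coordinates."""
import sys

import numpy as np
import umap


def main() -> None:
    inp, outp, n_neighbors, min_dist, seed = sys.argv[1:6]
    X = np.loadtxt(inp, delimiter="\t", ndmin=2)
    reducer = umap.UMAP(
        n_neighbors=int(n_neighbors),
        min_dist=float(min_dist),
        random_state=int(seed),
    )
    emb = reducer.fit_transform(X)
    np.savetxt(outp, emb, delimiter="\t")


if __name__ == "__main__":
    main()
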