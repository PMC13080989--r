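"""Independent CBU-joining oracle built on RDKit molzip.

Reads a JSON list of candidates from stdin. Each candidate:
  {"fragments": [smiles, ...],   # slot order: bg, linkers..., bg-or-node
   "bits": [0/1 per linker],     # which linker dummy bonds to the previous
                                  # fragment (dummy order = RDKit atom order)
   "arrangement": "two_linear" | "two_bent" | "three_planar"}
Writes a JSON list of canonical product SMILES to stdout.
"""
import sys
import json
from rdkit import Chem, RDLogger

RDLogger.DisableLog("rdApp.*")


def dummies(mol):
    return [a.GetIdx() for a in mol.GetAtoms() if a.GetAtomicNum() == 0]


def label(mol, dummy_idx, map_num):
    mol.GetAtomWithIdx(dummy_idx).SetAtomMapNum(map_num)


def join_chain(frag_smis, bits):
    """bg + linkers in sequence; returns (mol, open dummy map num)."""
    next_map = 1
    bg = Chem.RWMol(Chem.MolFromSmiles(frag_smis[0]))
    d = dummies(bg)
    assert len(d) == 1
    label(bg, d[0], next_map)
    combined = bg.GetMol()
    open_map = next_map
    next_map += 1
    for k, smi in enumerate(frag_smis[1:]):
        lk = Chem.RWMol(Chem.MolFromSmiles(smi))
        d = dummies(lk)
        assert len(d) == 2
        first, second = (d[0], d[1]) if bits[k] == 0 else (d[1], d[0])
        label(lk, first, open_map)
        new_open = next_map
        next_map += 1
        label(lk, second, new_open)
        combined = Chem.molzip(Chem.CombineMols(combined, lk.GetMol()))
        open_map = new_open
    return combined, open_map, next_map


def assemble(cand):
    frags = cand["fragments"]
    bits = cand["bits"]
    if cand["arrangement"] == "three_planar":
        node = Chem.RWMol(Chem.MolFromSmiles(frags[-1]))
        nd = dummies(node)
        combined = None
        next_base = 100
        for site_i, didx in enumerate(nd):
            arm, open_map, _ = join_chain(frags[:-1], bits)
            # renumber the arm's open map to a node-specific number
            for a in arm.GetAtoms():
                if a.GetAtomMapNum() == open_map:
                    a.SetAtomMapNum(next_base + site_i)
            label(node, didx, next_base + site_i)
            combined = arm if combined is None else Chem.CombineMols(combined, arm)
        combined = Chem.molzip(Chem.CombineMols(combined, node.GetMol()))
    else:
        chain, open_map, next_map = join_chain(frags[:-1], bits)
        bg2 = Chem.RWMol(Chem.MolFromSmiles(frags[-1]))
        d = dummies(bg2)
        assert len(d) == 1
        label(bg2, d[0], open_map)
        combined = Chem.molzip(Chem.CombineMols(chain, bg2.GetMol()))
    for a in combined.GetAtoms():
        a.SetAtomMapNum(0)
    # enumeration counts constitutional isomers: the SMILES-level joiner is
    # stereo-agnostic, so the oracle strips stereo before canonicalizing
    Chem.RemoveStereochemistry(combined)
    return Chem.MolToSmiles(combined)


def main():
    cands = json.load(sys.stdin)
    print(json.dumps([assemble(c) for c in cands]))


if __name__ == "__main__":
    main()
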