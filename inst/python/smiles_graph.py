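"""Batch SMILES -> atom/bond records, one JSON object per input line.

Reads SMILES strings (one per line) from stdin and writes, for each, a single
line of JSON to stdout:

  {"ok": true,
   "atoms": [[Z, formal_charge, hyb, in_ring, aromatic, chirality], ...],
   "bonds": [[i, j, cls], ...]}

or, when RDKit cannot parse the string:

  {"ok": false, "error": "..."}

Codes (kept numeric to keep the stream compact):
  hyb:       0=S 1=SP 2=SP2 3=SP3 4=SP3D 5=SP3D2 6=Other
  chirality: 0=Unspecified 1=Clockwise(@@, CW) 2=Counter-clockwise(@, CCW) 3=Other
  cls:       1=single 2=double 3=triple 4=aromatic
Atom indices i, j are 0-based in RDKit atom order; hydrogens stay implicit.
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

HYB = {
    Chem.HybridizationType.S: 0,
    Chem.HybridizationType.SP: 1,
    Chem.HybridizationType.SP2: 2,
    Chem.HybridizationType.SP3: 3,
    Chem.HybridizationType.SP3D: 4,
    Chem.HybridizationType.SP3D2: 5,
}

CHI = {
    Chem.ChiralType.CHI_UNSPECIFIED: 0,
    Chem.ChiralType.CHI_TETRAHEDRAL_CW: 1,
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW: 2,
}

BOND = {
    Chem.BondType.SINGLE: 1,
    Chem.BondType.DOUBLE: 2,
    Chem.BondType.TRIPLE: 3,
    Chem.BondType.AROMATIC: 4,
}


def mol_record(smiles):
    mol = Chem.MolFromSmiles(smiles)  # sanitizes + perceives aromaticity
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES"}
    atoms = []
    for a in mol.GetAtoms():
        atoms.append([
            a.GetAtomicNum(),
            a.GetFormalCharge(),
            HYB.get(a.GetHybridization(), 6),
            1 if a.IsInRing() else 0,
            1 if a.GetIsAromatic() else 0,
            CHI.get(a.GetChiralTag(), 3),
        ])
    bonds = []
    for b in mol.GetBonds():
        cls = BOND.get(b.GetBondType())
        if cls is None:
            # dative/quadruple/etc. never arise from plain organic SMILES
            return {"ok": False, "error": "unsupported bond type %s" % b.GetBondType()}
        bonds.append([b.GetBeginAtomIdx(), b.GetEndAtomIdx(), cls])
    return {"ok": True, "atoms": atoms, "bonds": bonds}


def main():
    out = sys.stdout
    for line in sys.stdin:
        smiles = line.rstrip("\n")
        try:
            rec = mol_record(smiles)
        except Exception as exc:  # pragma: no cover - defensive
            rec = {"ok": False, "error": str(exc)}
        out.write(json.dumps(rec, separators=(",", ":")))
        out.write("\n")
    out.flush()


if __name__ == "__main__":
    main()
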