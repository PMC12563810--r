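"""Batched SMILES perception backend.

Reads one SMILES per line from the file given as argv[1] and writes one JSON
object per molecule (a JSON array overall) to stdout:
  {"ok": true, "atoms": {"symbol": [...], "degree": [...], ...},
   "bonds": [[i, j, order], ...]}   (i, j are 1-based atom indices)
or {"ok": false, "error": "..."} for unparsable input. Chemical perception
(aromaticity, implicit hydrogens) is RDKit's default sanitization; hydrogens
stay implicit so nodes are heavy atoms only.
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

HYB = {
    Chem.HybridizationType.SP: "SP",
    Chem.HybridizationType.SP2: "SP2",
    Chem.HybridizationType.SP3: "SP3",
    Chem.HybridizationType.SP3D: "SP3D",
    Chem.HybridizationType.SP3D2: "SP3D2",
}

BOND_ORDER = {
    Chem.BondType.SINGLE: 1.0,
    Chem.BondType.DOUBLE: 2.0,
    Chem.BondType.TRIPLE: 3.0,
    Chem.BondType.AROMATIC: 1.5,
}


def perceive(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES"}
    atoms = {
        "symbol": [], "degree": [], "implicit_h": [], "formal_charge": [],
        "radical_electrons": [], "hybridization": [], "total_h": [],
        "aromatic": [],
    }
    for a in mol.GetAtoms():
        atoms["symbol"].append(a.GetSymbol())
        atoms["degree"].append(a.GetDegree())
        atoms["implicit_h"].append(a.GetNumImplicitHs())
        atoms["formal_charge"].append(a.GetFormalCharge())
        atoms["radical_electrons"].append(a.GetNumRadicalElectrons())
        atoms["hybridization"].append(HYB.get(a.GetHybridization(), "OTHER"))
        atoms["total_h"].append(a.GetTotalNumHs())
        atoms["aromatic"].append(bool(a.GetIsAromatic()))
    bonds = [
        [b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
         BOND_ORDER.get(b.GetBondType(), 1.0)]
        for b in mol.GetBonds()
    ]
    return {"ok": True, "atoms": atoms, "bonds": bonds}


def main():
    with open(sys.argv[1]) as fh:
        smiles_list = [line.rstrip("\n") for line in fh]
    json.dump([perceive(s) for s in smiles_list], sys.stdout)


if __name__ == "__main__":
    main()
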