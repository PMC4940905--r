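# comodiff

Computational models of biological systems — SBML reaction networks,
CellML physiological models — live in open repositories and change over
time: parameters are retuned, species renamed, reactions added, the
encoding upgraded to a newer format level. A plain XML diff can list these
edits, but it cannot say *what kind* of change each edit is, which makes it
hard to decide whether a new version still reproduces published results or
merely reflects serialization churn.

`comodiff` computes the **delta** between two versions of an XML-encoded
model — an ordered set of *Insertion*, *Deletion*, *Update* and *Move*
operations on XML entities sufficient to transform one document into the
other — and annotates every operation with terms from the **COMODI**
change ontology:

* the change type (`Insertion`, `Deletion`, `Update`, `Move`),
* the XML entity it applies to (`appliesTo`: `XmlNode`, `XmlAttribute`,
  `XmlText`),
* the model layers it affects (`affects`: `ModelEncoding`,
  `ModelAnnotation`, `ModelDefinition`, `ModelSetup`, `ModelBehaviour` and
  their refinements such as `ParameterSetup` or `KineticsDefinition`),
* user-supplied intention and reason (`hasIntention`, `hasReason`, e.g.
  `Correction` of a `Typo`),
* causal links between changes (`wasTriggeredBy`: deleting a reaction
  triggers the deletion of its kinetic law).

Annotations are serialized as RDF/Turtle in a file independent of the diff
XML, and change sets can be filtered by ontology term with subsumption
(asking for `ModelSetup` changes also returns `ParameterSetup` changes),
including suppressing order-only element reshuffling and collapsing a
version series to the versions that carry relevant changes. The intended
users are model curators, modellers and tool developers who need to audit
or display model histories.

## Worked example

Two versions of a minimal SBML model in which the parameter `Km1` changes
from 23.24 to 23.42 molesperlitre:

```r
library(comodiff)

a <- model_from_xml(
  '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
     <model id="m"><listOfParameters>
       <parameter id="Km1" value="23.24" units="molesperlitre"/>
     </listOfParameters></model></sbml>')
b <- model_from_xml(gsub("23.24", "23.42", model_to_xml(a), fixed = TRUE))

delta <- diff_models(a, b)
delta
#> <model_delta> memory -> memory (dialect=sbml): 1 operations
#>    Insertion=0 Deletion=0 Update=1 Move=0
#>   op1 Update XmlAttribute /sbml[1]/model[1]/listOfParameters[1]/parameter[1] @value '23.24' -> '23.42'
```

The single operation is an `Update` of an `XmlAttribute`: the `value`
attribute of the `Km1` parameter, with the old and new values recorded.
Annotating it classifies the affected model layer automatically; intention
and reason are supplied by the user:

```r
anns <- annotate_delta(delta, user_annotations = list(
  op1 = list(has_intention = "Correction", has_reason = "MismatchWithPublication")))
anns
#> <change_annotations> 1 annotated changes
#>   op1 Update appliesTo=XmlAttribute affects=ParameterSetup intention=Correction reason=MismatchWithPublication

cat(annotations_to_turtle(anns, delta_ref = "delta.xml"))
#> @prefix comodi: <http://purl.uni-rostock.de/comodi/comodi#> .
#> @prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
#>
#> <delta.xml#op1> rdf:type comodi:Update ;
#>     comodi:appliesTo comodi:XmlAttribute ;
#>     comodi:affects comodi:ParameterSetup ;
#>     comodi:hasIntention comodi:Correction ;
#>     comodi:hasReason comodi:MismatchWithPublication .
```

`affects=ParameterSetup` says the change touches the simulation setup; by
subsumption it also affects `ModelSetup`, so
`filter_changes(anns, filter_profile(include = "ModelSetup"))` keeps it.
`apply_delta(a, delta)` reproduces version `b` exactly (canonical XML
equality) — the defining contract of the delta.

## Command line

The same pipeline is available as an `Rscript` tool (installed under
`exec/comodi` in the package library):

```sh
comodi diff a.xml b.xml -o delta.xml          # exit 1 if differences
comodi annotate delta.xml --user-annotations notes.yaml -o changes.ttl
comodi filter changes.ttl --include ChangedSpecification -o spec-changes.ttl
comodi vocab export -o comodi-core.ttl
comodi fixtures --mutation typo_rename --seed 1 -o fixtures/
```

## Further reading

The methods vignette (`vignettes/model-diff-annotation.Rmd`) documents the
matching algorithm, the patch semantics, the classification rule tables,
the synthetic fixture generator and the design decisions behind them.
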