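kind	tag	attribute	targets
element	math	*	KineticsDefinition
element	variable	*	ModelDefinition
element	component	*	ModelDefinition
element	connection	*	ModelDefinition
element	map_variables	*	ModelDefinition
element	map_components	*	ModelDefinition
element	group	*	ModelDefinition
element	relationship_ref	*	ModelDefinition
element	component_ref	*	ModelDefinition
element	units	*	ModelDefinition
element	rdf:RDF	*	ModelAnnotation
element	documentation	*	ModelAnnotation
attribute	*	initial_value	ParameterSetup
attribute	*	name	EntityName
attribute	*	cmeta:id	EntityIdentifier
attribute	*	id	EntityIdentifier
namespace	*	*	ModelEncoding
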