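kind	tag	attribute	targets
element	parameter	*	ParameterSetup
element	localParameter	*	ParameterSetup
element	listOfParameters	*	ParameterSetup
element	kineticLaw	*	KineticsDefinition
element	functionDefinition	*	FunctionDefinition
element	listOfFunctionDefinitions	*	FunctionDefinition
element	annotation	*	ModelAnnotation
element	rdf:RDF	*	ModelAnnotation
element	notes	*	ModelAnnotation
element	species	*	ReactionNetworkDefinition
element	reaction	*	ReactionNetworkDefinition
element	speciesReference	*	ReactionNetworkDefinition
element	modifierSpeciesReference	*	ReactionNetworkDefinition
element	listOfReactants	*	ReactionNetworkDefinition
element	listOfProducts	*	ReactionNetworkDefinition
element	listOfModifiers	*	ReactionNetworkDefinition
element	listOfSpecies	*	ReactionNetworkDefinition
element	listOfReactions	*	ReactionNetworkDefinition
element	compartment	*	ReactionNetworkDefinition
element	listOfCompartments	*	ReactionNetworkDefinition
element	unitDefinition	*	ModelDefinition
element	listOfUnitDefinitions	*	ModelDefinition
element	rule	*	ModelDefinition
element	listOfRules	*	ModelDefinition
element	event	*	ModelDefinition
element	listOfEvents	*	ModelDefinition
attribute	*	name	EntityName
attribute	*	id	EntityIdentifier
attribute	*	metaid	EntityIdentifier
attribute	sbml	level	ModelEncoding
attribute	sbml	version	ModelEncoding
namespace	*	*	ModelEncoding
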