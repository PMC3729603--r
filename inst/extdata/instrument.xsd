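<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema of record for the instrument dialect, in the canonical element
     order that serialize_instrument() emits.  The parser is additionally
     lenient about element order within a parent on input. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">

  <xs:complexType name="localizedText">
    <xs:simpleContent>
      <xs:extension base="xs:string">
        <xs:attribute name="lang" type="xs:string"/>
      </xs:extension>
    </xs:simpleContent>
  </xs:complexType>

  <xs:complexType name="itemType">
    <xs:sequence>
      <xs:element name="description" type="localizedText" maxOccurs="unbounded"/>
      <xs:element name="media" type="xs:string" minOccurs="0"/>
      <xs:element name="scoringCategory" type="xs:string"/>
    </xs:sequence>
    <xs:attribute name="id" type="xs:string" use="required"/>
    <xs:attribute name="number" type="xs:nonNegativeInteger" use="required"/>
  </xs:complexType>

  <xs:complexType name="itemList">
    <xs:sequence>
      <xs:element name="item" type="itemType" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="responseType">
    <xs:sequence>
      <xs:element name="label" type="localizedText" minOccurs="0"
                  maxOccurs="unbounded"/>
    </xs:sequence>
    <xs:attribute name="id" type="xs:string" use="required"/>
    <xs:attribute name="label" type="xs:string"/>
  </xs:complexType>

  <xs:element name="instrument">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="instrumentPolicies" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="requireRespondentId" type="xs:string" minOccurs="0"/>
              <xs:element name="requireVisitCode" type="xs:string" minOccurs="0"/>
              <xs:element name="requireVideoViewing" type="xs:string" minOccurs="0"/>
              <xs:element name="startVideoAutomatically" type="xs:string" minOccurs="0"/>
              <xs:element name="serverSubmissionURL" type="xs:anyURI" minOccurs="0"/>
              <xs:element name="showComputedScore" type="xs:string" minOccurs="0"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="instructions" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="instructionText" type="localizedText"
                          maxOccurs="unbounded"/>
              <xs:element name="practiceItems" type="itemList" minOccurs="0"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="items" type="itemList"/>
        <xs:element name="scoring">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="categories">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="category" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="responses">
                            <xs:complexType>
                              <xs:sequence>
                                <xs:element name="response" type="responseType"
                                            maxOccurs="unbounded"/>
                              </xs:sequence>
                            </xs:complexType>
                          </xs:element>
                          <xs:element name="mappingFunction" type="xs:string"
                                      minOccurs="0"/>
                        </xs:sequence>
                        <xs:attribute name="id" type="xs:string" use="required"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="scoreComputation" minOccurs="0">
                <xs:complexType>
                  <xs:choice>
                    <xs:element name="lookupTable" type="xs:string"/>
                    <xs:element name="scoringFunction" type="xs:string"/>
                    <xs:element name="catTree" type="xs:string"/>
                  </xs:choice>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
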