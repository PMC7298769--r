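<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">

  <xs:simpleType name="identifier">
    <xs:restriction base="xs:string">
      <xs:pattern value="[A-Za-z_][A-Za-z0-9_.-]*"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="valueType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="string"/>
      <xs:enumeration value="integer"/>
      <xs:enumeration value="double"/>
      <xs:enumeration value="boolean"/>
      <xs:enumeration value="file"/>
      <xs:enumeration value="folder"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:attributeGroup name="versionRange">
    <xs:attribute name="minVersion" type="xs:positiveInteger"/>
    <xs:attribute name="maxVersion" type="xs:positiveInteger"/>
  </xs:attributeGroup>

  <xs:element name="module">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="command" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="arg" type="xs:string" maxOccurs="unbounded"/>
            </xs:sequence>
            <xs:attributeGroup ref="versionRange"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="parameter" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="name" type="identifier" use="required"/>
            <xs:attribute name="type" type="valueType"/>
            <xs:attribute name="required" type="xs:boolean"/>
            <xs:attribute name="default" type="xs:string"/>
            <xs:attribute name="checkExistence" type="xs:boolean"/>
            <xs:attributeGroup ref="versionRange"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="return" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="name" type="identifier" use="required"/>
            <xs:attribute name="type" type="valueType"/>
            <xs:attributeGroup ref="versionRange"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="name" type="identifier" use="required"/>
      <xs:attribute name="maxVersion" type="xs:positiveInteger"/>
      <xs:attribute name="versionFlag" type="xs:string"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
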